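#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML variance-component fit
#'
#' @param x An `mmra_varcomp`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.mmra_varcomp <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_a2", "sigma_e2", "h2", "mu"),
    estimate = c(x$sigma_a2, x$sigma_e2, x$h2, x$mu_hat)
  )
}

#' @rdname tidy.mmra_varcomp
#' @return For `glance()`: a one-row model summary.
#' @export
glance.mmra_varcomp <- function(x, ...) {
  tibble::tibble(
    sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2, h2 = x$h2,
    lambda = x$lambda, loglik = x$loglik, n = x$n,
    converged = x$converged, boundary = x$boundary
  )
}

#' Tidy a genome scan
#'
#' The scan is already tibble-shaped; `tidy()` strips the class and
#' attributes, `glance()` gives a one-row summary.
#'
#' @param x An `mmra_scan`.
#' @param ... Unused.
#' @export
tidy.mmra_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mmra_scan")
  attr(out, "vc") <- attr(out, "rotation") <- NULL
  out
}

#' @rdname tidy.mmra_scan
#' @export
glance.mmra_scan <- function(x, ...) {
  vc <- attr(x, "vc")
  tibble::tibble(
    n_snps = nrow(x),
    n_individuals = attr(x, "n_individuals"),
    n_tested = sum(!is.na(x$wald)),
    min_p = min(x$p_raw, na.rm = TRUE),
    top_snp = x$snp[which.min(x$p_raw)],
    sigma_a2 = vc$sigma_a2, sigma_e2 = vc$sigma_e2, h2 = vc$h2
  )
}
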