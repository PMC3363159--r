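#' Map phenotype records to pedigree positions
#'
#' The animal-model incidence matrix Z has one row per phenotype record and
#' one column per pedigree member, with a single 1 per row; here it is
#' represented compactly as the integer vector of pedigree positions, so
#' that `Z A Z'` is `A[idx, idx]`.
#'
#' @param pedigree A `ped_tbl`.
#' @param trait A `trait_tbl` (columns `id`, `value`) or any data frame with
#'   those columns.
#' @return Integer vector of pedigree positions, one per trait record.
#' @export
incidence_Z <- function(pedigree, trait) {
  if (anyDuplicated(trait$id)) {
    stop("repeated phenotype records are not supported: ",
         trait$id[duplicated(trait$id)][1], call. = FALSE)
  }
  idx <- match(trait$id, pedigree$id)
  if (anyNA(idx)) {
    stop("phenotyped id(s) absent from pedigree: ",
         paste(utils::head(trait$id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Spectral cache for the animal model
#'
#' One-time eigendecomposition of `K = Z A Z'` (the relationship matrix
#' restricted to the phenotyped individuals). Both the REML profile
#' likelihood and the association scan reuse it, turning every evaluation
#' into diagonal arithmetic.
#'
#' @param A Additive relationship matrix with ids as dimnames.
#' @param idx Pedigree positions of the phenotyped records (from
#'   [incidence_Z()]), or a character vector of ids.
#' @return List with eigenvectors `U`, eigenvalues `d`, the rotated
#'   intercept `xstar`, and `n`.
#' @export
reml_spectral_cache <- function(A, idx) {
  if (is.character(idx)) idx <- match(idx, rownames(A))
  K <- A[idx, idx, drop = FALSE]
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  list(U = e$vectors, d = pmax(e$values, 0), xstar = crossprod(e$vectors, rep(1, nrow(K))),
       n = nrow(K))
}

#' Profiled restricted log-likelihood of the variance ratio
#'
#' For the model `y = 1 mu + Z a + e` with `a ~ N(0, A sigma_a^2)` and
#' `e ~ N(0, I sigma_e^2)`, the marginal covariance is
#' `V = sigma_e^2 (lambda K + I)` with `lambda = sigma_a^2 / sigma_e^2` and
#' `K = Z A Z'`. Given the eigendecomposition of K, the residual variance is
#' profiled out analytically and the full restricted log-likelihood is
#' returned as a function of `lambda` alone.
#'
#' @param lambda_ratio Non-negative variance ratio `sigma_a^2 / sigma_e^2`.
#' @param cache A [reml_spectral_cache()].
#' @param y Numeric phenotype vector aligned with the cache.
#' @return The restricted log-likelihood at `lambda_ratio` with
#'   `sigma_e^2` at its conditional maximum; attributes `sigma_e2` and
#'   `mu_hat` carry the profiled values.
#' @export
restricted_loglik <- function(lambda_ratio, cache, y) {
  if (lambda_ratio < 0) stop("lambda_ratio must be non-negative", call. = FALSE)
  n <- cache$n
  p <- 1L
  v <- lambda_ratio * cache$d + 1
  w <- 1 / v
  ystar <- crossprod(cache$U, y)
  xs <- cache$xstar
  xtwx <- sum(w * xs^2)
  xtwy <- sum(w * xs * ystar)
  ytwy <- sum(w * ystar^2)
  rss <- ytwy - xtwy^2 / xtwx
  sigma_e2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma_e2) + sum(log(v)) + log(xtwx) +
                  (n - p) + (n - p) * log(2 * pi))
  attr(ll, "sigma_e2") <- sigma_e2
  attr(ll, "mu_hat") <- xtwy / xtwx
  ll
}

#' REML estimation of additive and residual variance
#'
#' Fits the intercept-only animal model `y = 1 mu + Z a + e` by restricted
#' maximum likelihood, maximising the profiled criterion of
#' [restricted_loglik()] over the variance ratio by bounded one-dimensional
#' optimisation (Brent on the log-ratio scale), then back-solving the
#' residual and additive variances. A single eigendecomposition of
#' `Z A Z'` makes every likelihood evaluation O(n).
#'
#' A fit whose ratio lands on the lower search bound is reported with
#' `sigma_a2` clipped to the boundary and `boundary = TRUE` rather than an
#' error: null traits legitimately estimate zero additive variance.
#'
#' @param trait A `trait_tbl` (columns `id`, `value`).
#' @param A Additive relationship matrix covering the pedigree.
#' @param pedigree A `ped_tbl`.
#' @param lambda_bounds Search interval for `sigma_a^2 / sigma_e^2`
#'   (default `c(1e-6, 1e3)`).
#' @param tol Convergence tolerance of the optimiser (default 1e-6).
#' @param cache Optional precomputed [reml_spectral_cache()].
#' @param keep_cache Keep the spectral cache on the returned object (used to
#'   avoid recomputing it for the association scan)? Default `TRUE`.
#' @return An object of class `mmra_varcomp`: `sigma_a2`, `sigma_e2`, `h2`,
#'   `lambda`, `loglik`, `mu_hat`, `converged`, `boundary`, `n`.
#' @examples
#' \donttest{
#' pop <- simulate_population(sim_config(
#'   n_sires = 10, n_dams_per_sire = 4, n_progeny_per_dam = 6,
#'   n_phenotyped_per_dam = 6, snps_per_chromosome = 100, seed = 2
#' ))
#' A <- build_A(pop$pedigree)
#' estimate_variance_components(pop$phenotypes, A, pop$pedigree)
#' }
#' @export
estimate_variance_components <- function(trait, A, pedigree,
                                         lambda_bounds = c(1e-6, 1e3),
                                         tol = 1e-6,
                                         cache = NULL,
                                         keep_cache = TRUE) {
  idx <- incidence_Z(pedigree, trait)
  y <- trait$value
  if (length(y) < 2L) stop("need at least two phenotype records", call. = FALSE)
  if (is.null(cache)) cache <- reml_spectral_cache(A, idx)

  # identifiability: Z A Z' must differ from the identity
  if (max(abs(cache$d - 1)) < 1e-8) {
    stop("no relatedness among phenotyped individuals: ",
         "additive and residual variance are not separately identifiable",
         call. = FALSE)
  }

  obj <- function(loglam) as.numeric(restricted_loglik(exp(loglam), cache, y))
  opt <- stats::optimize(obj, interval = log(lambda_bounds),
                         maximum = TRUE, tol = tol)
  lambda <- exp(opt$maximum)
  ll_hat <- restricted_loglik(lambda, cache, y)

  boundary <- FALSE
  ll0 <- restricted_loglik(0, cache, y)
  if (as.numeric(ll0) >= as.numeric(ll_hat)) {
    lambda <- 0
    ll_hat <- ll0
    boundary <- TRUE
  } else if (lambda <= lambda_bounds[1] * 1.01) {
    boundary <- TRUE
  }

  sigma_e2 <- attr(ll_hat, "sigma_e2")
  sigma_a2 <- max(lambda * sigma_e2, 0)
  out <- structure(list(
    sigma_a2 = sigma_a2,
    sigma_e2 = sigma_e2,
    h2 = sigma_a2 / (sigma_a2 + sigma_e2),
    lambda = lambda,
    loglik = as.numeric(ll_hat),
    mu_hat = attr(ll_hat, "mu_hat"),
    converged = TRUE,
    boundary = boundary,
    n = cache$n
  ), class = "mmra_varcomp")
  if (keep_cache) attr(out, "cache") <- cache
  out
}

#' Profile-likelihood confidence interval for the variance ratio
#'
#' Inverts the restricted likelihood-ratio statistic
#' `2 (l(lambda_hat) - l(lambda)) <= qchisq(level, 1)` on a log-spaced grid.
#'
#' @param fit An `mmra_varcomp` fitted with `keep_cache = TRUE`.
#' @param trait The trait used in the fit.
#' @param level Coverage (default 0.95).
#' @param grid_n Grid resolution (default 400).
#' @return Numeric `c(lower, upper)` for `lambda`.
#' @export
reml_profile_ci <- function(fit, trait, level = 0.95, grid_n = 400) {
  cache <- attr(fit, "cache")
  if (is.null(cache)) stop("fit was made with keep_cache = FALSE", call. = FALSE)
  y <- trait$value
  cut <- stats::qchisq(level, 1) / 2
  grid <- c(0, exp(seq(log(1e-6), log(1e3), length.out = grid_n)))
  ll <- vapply(grid, function(l) as.numeric(restricted_loglik(l, cache, y)),
               numeric(1))
  ok <- fit$loglik - ll <= cut
  c(lower = min(grid[ok]), upper = max(grid[ok]))
}

#' @export
print.mmra_varcomp <- function(x, ...) {
  cat("Animal-model REML variance components\n")
  cat(sprintf("  sigma_a^2: %.4f\n", x$sigma_a2))
  cat(sprintf("  sigma_e^2: %.4f\n", x$sigma_e2))
  cat(sprintf("  h^2:       %.4f\n", x$h2))
  cat(sprintf("  records:   %d%s\n", x$n,
              if (x$boundary) "  (boundary estimate)" else ""))
  invisible(x)
}
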