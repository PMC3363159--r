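#' Upper-tail chi-squared p-value of a Wald statistic
#'
#' @param wald Non-negative Wald chi-squared statistic(s), df = 1.
#' @return Upper-tail probability under chi-squared(1).
#' @examples
#' wald_pvalue(3.841459) # ~0.05
#' @export
wald_pvalue <- function(wald) {
  if (any(wald < 0, na.rm = TRUE)) {
    stop("Wald statistic must be non-negative", call. = FALSE)
  }
  stats::pchisq(wald, df = 1, lower.tail = FALSE)
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha Genome-wide significance level in (0, 1).
#' @param n_tests Number of tests (retained SNPs), at least 1.
#' @return The per-test raw p-value threshold `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 6396) # 7.82e-06
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Mixed-model regression for a single SNP
#'
#' Fits `y = 1 mu + b x + Z a + e` with the variance components held at
#' their REML estimates, by generalised least squares with
#' `V = K sigma_a^2 + I sigma_e^2`, `K = Z A Z'`. This is the solution of
#' Henderson's mixed model equations for the fixed effects; the sampling
#' variance of `b` is the corresponding diagonal element of
#' `(X' V^-1 X)^-1`.
#'
#' @param y Phenotype vector (phenotyped individuals).
#' @param x Genotype codes 0/1/2 aligned with `y`; needs at least two
#'   distinct values.
#' @param A_phen Relationship matrix restricted to the phenotyped
#'   individuals (`K`).
#' @param vc An `mmra_varcomp` (or list with `sigma_a2`, `sigma_e2`).
#' @return One-row tibble: `b_hat`, `var_b`, `wald`, `p_raw`, `mu_hat`.
#' @export
fit_single_snp <- function(y, x, A_phen, vc) {
  n <- length(y)
  stopifnot(length(x) == n, nrow(A_phen) == n)
  if (length(unique(x)) < 2L) {
    stop("SNP has no genotype variation among phenotyped individuals",
         call. = FALSE)
  }
  V <- vc$sigma_a2 * A_phen + diag(vc$sigma_e2, n)
  X <- cbind(mu = 1, b = x)
  ch <- chol(V)
  Vx <- backsolve(ch, forwardsolve(t(ch), X))
  Vy <- backsolve(ch, forwardsolve(t(ch), y))
  XtVX <- crossprod(X, Vx)
  XtVy <- crossprod(X, Vy)
  C <- solve(XtVX)
  beta <- unname(drop(C %*% XtVy))
  var_b <- unname(C[2, 2])
  wald <- beta[2]^2 / var_b
  tibble::tibble(b_hat = beta[2], var_b = var_b, wald = wald,
                 p_raw = wald_pvalue(wald), mu_hat = beta[1])
}

# Precompute everything the per-SNP weighted regressions need after the
# one-time spectral rotation: with V = sigma_e^2 (lambda K + I) and
# K = U diag(d) U', rotating y and the design by U' gives independent
# observations with weights w = 1 / (lambda d + 1).
scan_rotation <- function(genotypes, trait, A, vc, cache = NULL) {
  ids <- trait$id
  if (is.null(rownames(genotypes))) {
    stop("genotype matrix must have individual ids as rownames", call. = FALSE)
  }
  ridx <- match(ids, rownames(genotypes))
  if (anyNA(ridx)) {
    stop("phenotyped id(s) absent from genotype matrix: ",
         paste(utils::head(ids[is.na(ridx)], 5), collapse = ", "),
         call. = FALSE)
  }
  G <- genotypes[ridx, , drop = FALSE]
  if (is.null(cache)) cache <- attr(vc, "cache")
  if (is.null(cache)) {
    aidx <- match(ids, rownames(A))
    if (anyNA(aidx)) stop("phenotyped id(s) absent from A", call. = FALSE)
    cache <- reml_spectral_cache(A, aidx)
  }
  lambda <- vc$sigma_a2 / vc$sigma_e2
  w <- 1 / (lambda * cache$d + 1)
  u <- drop(cache$xstar)                       # rotated intercept
  mono <- unname(apply(G, 2L, function(col) length(unique(col)) < 2L))
  Gstar <- crossprod(cache$U, G)               # rotated genotype columns
  wu <- w * u
  a11 <- sum(wu * u)
  a12 <- unname(drop(crossprod(Gstar, wu)))
  a22 <- unname(colSums(w * Gstar^2))
  det <- a11 * a22 - a12^2
  list(U = cache$U, w = w, u = u, Gstar = Gstar,
       a11 = a11, a12 = a12, a22 = a22, det = det,
       mono = mono, sigma_e2 = vc$sigma_e2, n = length(ids))
}

# Wald statistics for one phenotype vector against all rotated SNPs.
scan_stats <- function(rot, y) {
  ystar <- drop(crossprod(rot$U, y))
  wy <- rot$w * ystar
  b1 <- sum(rot$u * wy)
  b2 <- unname(drop(crossprod(rot$Gstar, wy)))
  b_hat <- (rot$a11 * b2 - rot$a12 * b1) / rot$det
  var_b <- rot$sigma_e2 * rot$a11 / rot$det
  wald <- b_hat^2 / var_b
  b_hat[rot$mono] <- NA_real_
  var_b[rot$mono] <- NA_real_
  wald[rot$mono] <- NA_real_
  list(b_hat = b_hat, var_b = var_b, wald = wald)
}

#' Genome scan: per-SNP mixed-model Wald tests
#'
#' Tests every SNP with the single-locus mixed model
#' `y = 1 mu + b x + Z a + e`, holding the variance components fixed at the
#' REML estimates from the no-SNP model (a P3D/EMMAX-style scan). One
#' spectral rotation of the phenotypes and genotype columns by the
#' eigenvectors of `Z A Z'` reduces each SNP to a weighted two-covariate
#' regression, exactly equivalent to solving the mixed model equations per
#' SNP.
#'
#' SNPs without genotype variation among the phenotyped individuals (which
#' cannot occur after [filter_snps()] on the same individual set) are
#' returned as flagged `NA` records rather than aborting the scan.
#'
#' @param genotypes Genotype matrix (codes 0/1/2) with ids as rownames;
#'   typically the QC-filtered matrix.
#' @param snp_map Map tibble aligned with the genotype columns (columns
#'   `id`, `chromosome`, `pos_cM`, optionally `maf`).
#' @param trait A `trait_tbl` (columns `id`, `value`).
#' @param A Additive relationship matrix.
#' @param vc An `mmra_varcomp` from [estimate_variance_components()].
#' @param cache Optional [reml_spectral_cache()] (reused from the REML fit
#'   when present on `vc`).
#' @return A tibble of class `mmra_scan`, one row per SNP in map order:
#'   `snp`, `chromosome`, `pos_cM`, `maf`, `b_hat`, `se`, `wald`, `p_raw`.
#'   Attributes record the variance components and dimensions.
#' @export
mmra_scan <- function(genotypes, snp_map, trait, A, vc, cache = NULL) {
  stopifnot(nrow(snp_map) == ncol(genotypes))
  if (vc$sigma_a2 < 0 || vc$sigma_e2 <= 0) {
    stop("variance components must satisfy sigma_a2 >= 0, sigma_e2 > 0",
         call. = FALSE)
  }
  rot <- scan_rotation(genotypes, trait, A, vc, cache)
  st <- scan_stats(rot, trait$value)
  out <- tibble::tibble(
    snp = snp_map$id,
    chromosome = snp_map$chromosome,
    pos_cM = snp_map$pos_cM,
    maf = if ("maf" %in% names(snp_map)) snp_map$maf else
      minor_allele_frequency(genotypes[match(trait$id, rownames(genotypes)), ,
                                       drop = FALSE]),
    b_hat = st$b_hat,
    se = sqrt(st$var_b),
    wald = st$wald,
    p_raw = wald_pvalue(pmax(st$wald, 0))
  )
  class(out) <- c("mmra_scan", class(out))
  attr(out, "vc") <- vc[c("sigma_a2", "sigma_e2", "h2")]
  attr(out, "n_individuals") <- rot$n
  attr(out, "n_snps") <- nrow(out)
  attr(out, "rotation") <- rot
  out
}
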