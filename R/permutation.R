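#' Permute phenotype values among the phenotyped individuals
#'
#' Shuffles the trait values uniformly while leaving the id column (hence
#' the genotype and pedigree links) untouched; the multiset of values is
#' preserved exactly. Draws from the current RNG state.
#'
#' @param trait A `trait_tbl` (columns `id`, `value`).
#' @return The trait with `value` permuted.
#' @export
permute_phenotypes <- function(trait) {
  # sample.int avoids the sample() length-1 pitfall
  trait$value <- trait$value[sample.int(nrow(trait))]
  trait
}

#' Null distribution of the genome-wide maximum Wald statistic
#'
#' Permutes the phenotypes against the fixed genotypes and pedigree
#' `n_perm` times, rescans the genome with the variance components held at
#' their observed-data REML estimates, and records the largest Wald
#' chi-squared statistic of each permuted scan. Each permutation draws from
#' its own RNG stream seeded by `seed + permutation index`, so the result
#' is identical for any `workers` count.
#'
#' @inheritParams mmra_scan
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation streams.
#' @param workers Number of parallel processes (forked; 1 = serial).
#' @return An object of class `perm_null`: `n_perm`, `max_wald` (length
#'   `n_perm`), `seed`, `n_snps`.
#' @export
max_statistic_null <- function(genotypes, snp_map, trait, A, vc,
                               n_perm = 10000L, seed = 1L, workers = 1L,
                               cache = NULL) {
  stopifnot(n_perm >= 1)
  rot <- scan_rotation(genotypes, trait, A, vc, cache)
  y <- trait$value
  one_perm <- function(i) {
    set.seed((seed + i) %% .Machine$integer.max)
    st <- scan_stats(rot, sample(y))
    max(st$wald, na.rm = TRUE)
  }
  max_wald <- if (workers > 1L &&
                  requireNamespace("parallel", quietly = TRUE) &&
                  .Platform$OS.type == "unix") {
    unlist(parallel::mclapply(seq_len(n_perm), one_perm,
                              mc.cores = workers))
  } else {
    vapply(seq_len(n_perm), one_perm, numeric(1))
  }
  structure(list(n_perm = as.integer(n_perm), max_wald = max_wald,
                 seed = as.integer(seed), n_snps = ncol(genotypes)),
            class = "perm_null")
}

#' Empirical genome-wide Wald threshold
#'
#' The `ceiling((1 - alpha) * n_perm)`-th smallest of the per-permutation
#' maxima; a SNP is declared genome-wide significant when its observed Wald
#' statistic strictly exceeds this value.
#'
#' @param null A `perm_null` from [max_statistic_null()], or a numeric
#'   vector of per-permutation maxima.
#' @param alpha Genome-wide significance level in (0, 1); requires
#'   `n_perm * alpha >= 1`.
#' @return The Wald threshold (single number).
#' @examples
#' empirical_threshold(1:100, alpha = 0.05) # 95
#' @export
empirical_threshold <- function(null, alpha = 0.05) {
  max_wald <- if (inherits(null, "perm_null")) null$max_wald else null
  stopifnot(alpha > 0, alpha < 1)
  n <- length(max_wald)
  if (n * alpha < 1) {
    stop("too few permutations (", n, ") for alpha = ", alpha, call. = FALSE)
  }
  sort(max_wald)[ceiling((1 - alpha) * n)]
}

#' Permutation p-value for an observed maximum statistic
#'
#' `(1 + #{max_wald >= w_obs}) / (n_perm + 1)`; never smaller than
#' `1 / (n_perm + 1)`.
#'
#' @inheritParams empirical_threshold
#' @param w_obs Observed genome-wide maximum Wald statistic.
#' @return The empirical p-value.
#' @export
perm_pvalue <- function(null, w_obs) {
  max_wald <- if (inherits(null, "perm_null")) null$max_wald else null
  (1 + sum(max_wald >= w_obs)) / (length(max_wald) + 1)
}

#' Declare genome-wide significant SNPs
#'
#' @param scan_result An `mmra_scan` tibble.
#' @param threshold Wald threshold from [empirical_threshold()] (or any
#'   number); significance requires strict exceedance.
#' @return A list with `significant` (the qualifying scan rows) and
#'   `by_chromosome` (a tally tibble with a row per chromosome that carries
#'   at least one significant SNP).
#' @export
declare_significant <- function(scan_result, threshold) {
  sig <- dplyr::filter(scan_result, !is.na(.data$wald),
                       .data$wald > threshold)
  tally <- dplyr::count(sig, .data$chromosome, name = "n_significant")
  list(significant = sig, by_chromosome = tally, threshold = threshold)
}

#' @export
print.perm_null <- function(x, ...) {
  cat("Max-statistic permutation null\n")
  cat("  permutations:", x$n_perm, " SNPs:", x$n_snps, "\n")
  cat(sprintf("  max Wald quantiles: 50%% %.2f, 95%% %.2f, 99%% %.2f\n",
              stats::quantile(x$max_wald, 0.50),
              stats::quantile(x$max_wald, 0.95),
              stats::quantile(x$max_wald, 0.99)))
  invisible(x)
}
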