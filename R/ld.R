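# Two-locus LD from unphased genotypes: EM haplotype frequencies, D',
# likelihood confidence intervals, LOD, and Gabriel-criteria blocks.

# gamete types, in order: (1,1) (1,2) (2,1) (2,2) = alleles at locus i, j
GAMETE_A2_I <- c(0L, 0L, 1L, 1L)  # copies of allele 2 at locus i
GAMETE_A2_J <- c(0L, 1L, 0L, 1L)

# 3x3 genotype-class probabilities under random union of gametes
two_locus_class_probs <- function(h) {
  P <- matrix(0, 3, 3)
  for (g in 1:4) for (k in 1:4) {
    a <- GAMETE_A2_I[g] + GAMETE_A2_I[k]
    b <- GAMETE_A2_J[g] + GAMETE_A2_J[k]
    P[a + 1L, b + 1L] <- P[a + 1L, b + 1L] + h[g] * h[k]
  }
  P
}

two_locus_loglik <- function(counts, h) {
  P <- two_locus_class_probs(h)
  nz <- counts > 0
  sum(counts[nz] * log(pmax(P[nz], 1e-300)))
}

two_locus_counts <- function(geno_i, geno_j) {
  ok_i <- geno_i %in% 0:2
  ok_j <- geno_j %in% 0:2
  if (!all(ok_i) || !all(ok_j)) {
    stop("genotype codes must be 0, 1 or 2", call. = FALSE)
  }
  table(factor(geno_i, 0:2), factor(geno_j, 0:2))
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood frequencies of the four two-locus haplotypes from
#' unphased 0/1/2 genotype codes. Phase is ambiguous only for
#' double heterozygotes; the EM algorithm splits them between the coupling
#' (11/22) and repulsion (12/21) gamete pairs in proportion to the current
#' haplotype frequencies, starting from linkage equilibrium. All other
#' genotype classes contribute gametes by direct counting.
#'
#' @param geno_i,geno_j Aligned genotype vectors, codes 0/1/2 (count of
#'   allele 2).
#' @param tol Convergence tolerance on the largest frequency change
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return A list: `hap` (named frequencies `p11`, `p12`, `p21`, `p22`,
#'   allele 1 first), `p1`/`q1` (allele-1 frequencies at each locus),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `degenerate` (TRUE
#'   when either locus is monomorphic, in which case D' is undefined).
#' @examples
#' em_haplotype_freq(c(0, 1, 2, 2), c(0, 1, 2, 2))$hap
#' @export
em_haplotype_freq <- function(geno_i, geno_j, tol = 1e-8, max_iter = 1000L) {
  stopifnot(length(geno_i) == length(geno_j), length(geno_i) > 0)
  counts <- two_locus_counts(geno_i, geno_j)
  n <- length(geno_i)
  p1 <- 1 - sum(geno_i) / (2 * n)  # allele 1 frequency, locus i
  q1 <- 1 - sum(geno_j) / (2 * n)
  if (p1 %in% c(0, 1) || q1 %in% c(0, 1)) {
    return(list(hap = stats::setNames(rep(NA_real_, 4),
                                      c("p11", "p12", "p21", "p22")),
                p1 = p1, q1 = q1, loglik = NA_real_, loglik_trace = numeric(0),
                n_iter = 0L, converged = TRUE, degenerate = TRUE))
  }

  # unambiguous gamete counts (double heterozygotes handled by EM)
  cnt <- function(a, b) counts[a + 1L, b + 1L]
  c11 <- 2 * cnt(0, 0) + cnt(0, 1) + cnt(1, 0)
  c12 <- 2 * cnt(0, 2) + cnt(0, 1) + cnt(1, 2)
  c21 <- 2 * cnt(2, 0) + cnt(1, 0) + cnt(2, 1)
  c22 <- 2 * cnt(2, 2) + cnt(2, 1) + cnt(1, 2)
  n_dh <- cnt(1, 1)

  h <- c(p1 * q1, p1 * (1 - q1), (1 - p1) * q1, (1 - p1) * (1 - q1))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- h[1] * h[4] + h[2] * h[3]
    alpha <- if (denom > 0) h[1] * h[4] / denom else 0.5
    e <- c(c11 + n_dh * alpha, c12 + n_dh * (1 - alpha),
           c21 + n_dh * (1 - alpha), c22 + n_dh * alpha)
    h_new <- e / (2 * n)
    cmat <- as.matrix(counts)
    trace <- c(trace, two_locus_loglik(cmat, h_new))
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(hap = stats::setNames(h, c("p11", "p12", "p21", "p22")),
       p1 = p1, q1 = q1,
       loglik = two_locus_loglik(as.matrix(counts), h),
       loglik_trace = trace, n_iter = iter, converged = converged,
       degenerate = FALSE)
}

#' Normalised linkage disequilibrium D'
#'
#' `D = p11 - (p11 + p12)(p11 + p21)` is the coupling-gamete
#' disequilibrium; its maximum attainable magnitude given the allele
#' frequencies is `min(p1 q2, p2 q1)` when `D > 0` and
#' `min(p1 q1, p2 q2)` otherwise, and `D' = |D| / Dmax`.
#'
#' @param hap_freqs Numeric length-4 haplotype frequencies
#'   `(p11, p12, p21, p22)` summing to 1.
#' @return `D'` in `[0, 1]`, with attributes `D` and `Dmax`; `NA` with
#'   attribute `degenerate = TRUE` when either locus is monomorphic.
#' @examples
#' d_prime(c(0.4, 0.1, 0.1, 0.4)) # 0.6
#' @export
d_prime <- function(hap_freqs) {
  h <- unname(hap_freqs)
  if (anyNA(h)) return(structure(NA_real_, degenerate = TRUE))
  stopifnot(length(h) == 4, abs(sum(h) - 1) < 1e-6)
  p1 <- h[1] + h[2]; p2 <- 1 - p1
  q1 <- h[1] + h[3]; q2 <- 1 - q1
  D <- h[1] - p1 * q1
  dmax <- if (D > 0) min(p1 * q2, p2 * q1) else min(p1 * q1, p2 * q2)
  if (dmax <= 0) return(structure(NA_real_, degenerate = TRUE, D = D))
  structure(min(abs(D) / dmax, 1), D = D, Dmax = dmax)
}

# haplotype frequencies at a given signed D with allele freqs fixed
hap_at_D <- function(p1, q1, D) {
  h <- c(p1 * q1 + D, p1 * (1 - q1) - D, (1 - p1) * q1 - D,
         (1 - p1) * (1 - q1) + D)
  pmax(h, 0)
}

#' Likelihood confidence interval for D'
#'
#' Evaluates the multinomial likelihood of the nine two-locus genotype
#' classes on a grid of D' values in `[0, 1]` (allele frequencies fixed at
#' their sample estimates, the sign of D at its EM estimate), normalises
#' the likelihood over the grid, and reads the lower and upper bounds off
#' the cumulative weight at `(1 - coverage)/2` and `1 - (1 - coverage)/2`.
#' With the default `coverage = 0.90` these are the one-sided 5% and 95%
#' bounds used by the Gabriel block criteria.
#'
#' @inheritParams em_haplotype_freq
#' @param grid_step D' grid step (default 0.01).
#' @param coverage Two-sided coverage (default 0.90).
#' @return Named numeric `c(ci_low, ci_high)`; `NA`s for a degenerate pair.
#' @export
ld_confidence_interval <- function(geno_i, geno_j, grid_step = 0.01,
                                   coverage = 0.90) {
  em <- em_haplotype_freq(geno_i, geno_j)
  if (em$degenerate) return(c(ci_low = NA_real_, ci_high = NA_real_))
  counts <- as.matrix(two_locus_counts(geno_i, geno_j))
  dp_hat <- d_prime(em$hap)
  s <- if (!is.na(dp_hat) && attr(dp_hat, "D") < 0) -1 else 1
  p1 <- em$p1; q1 <- em$q1
  dmax <- if (s > 0) min(p1 * (1 - q1), (1 - p1) * q1) else
    min(p1 * q1, (1 - p1) * (1 - q1))
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, function(dp) {
    two_locus_loglik(counts, hap_at_D(p1, q1, s * dp * dmax))
  }, numeric(1))
  wt <- exp(ll - max(ll))
  cum <- cumsum(wt) / sum(wt)
  lo <- (1 - coverage) / 2
  hi <- 1 - lo
  c(ci_low = grid[which(cum >= lo)[1]], ci_high = grid[which(cum >= hi)[1]])
}

#' LOD score for pairwise LD
#'
#' Base-10 log likelihood ratio of the EM haplotype-frequency estimate
#' against linkage equilibrium (D = 0) with the same allele frequencies,
#' using the multinomial likelihood of the nine genotype classes.
#'
#' @inheritParams em_haplotype_freq
#' @return Non-negative LOD; `NA` for a degenerate pair.
#' @export
lod_score <- function(geno_i, geno_j) {
  em <- em_haplotype_freq(geno_i, geno_j)
  if (em$degenerate) return(NA_real_)
  counts <- as.matrix(two_locus_counts(geno_i, geno_j))
  ll0 <- two_locus_loglik(counts, hap_at_D(em$p1, em$q1, 0))
  max((em$loglik - ll0) / log(10), 0)
}

#' Pairwise LD summary for one SNP pair
#'
#' @inheritParams ld_confidence_interval
#' @return One-row tibble: haplotype frequencies, `D`, `d_prime`, `lod`,
#'   `ci_low`, `ci_high`, `degenerate`.
#' @export
ld_pair <- function(geno_i, geno_j, grid_step = 0.01, coverage = 0.90) {
  em <- em_haplotype_freq(geno_i, geno_j)
  if (em$degenerate) {
    return(tibble::tibble(p11 = NA_real_, p12 = NA_real_, p21 = NA_real_,
                          p22 = NA_real_, D = NA_real_, d_prime = NA_real_,
                          lod = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, degenerate = TRUE))
  }
  dp <- d_prime(em$hap)
  ci <- ld_confidence_interval(geno_i, geno_j, grid_step, coverage)
  tibble::tibble(
    p11 = em$hap[["p11"]], p12 = em$hap[["p12"]],
    p21 = em$hap[["p21"]], p22 = em$hap[["p22"]],
    D = if (is.na(dp)) NA_real_ else attr(dp, "D"),
    d_prime = as.numeric(dp),
    lod = lod_score(geno_i, geno_j),
    ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
    degenerate = is.na(dp)
  )
}

#' All pairwise LD among a set of SNPs
#'
#' @param genotypes Genotype matrix (codes 0/1/2) whose columns are the
#'   SNPs of interest (e.g. the significant SNPs of one chromosome).
#' @param snp_ids Columns to use (default all), in map order.
#' @inheritParams ld_confidence_interval
#' @return Tibble with `snp_i`, `snp_j` and the [ld_pair()] columns for
#'   every unordered pair (i before j in the supplied order).
#' @export
ld_pairs <- function(genotypes, snp_ids = colnames(genotypes),
                     grid_step = 0.01, coverage = 0.90) {
  m <- length(snp_ids)
  if (m < 2) stop("need at least two SNPs", call. = FALSE)
  combos <- utils::combn(m, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    dplyr::bind_cols(
      tibble::tibble(snp_i = snp_ids[i], snp_j = snp_ids[j]),
      ld_pair(genotypes[, snp_ids[i]], genotypes[, snp_ids[j]],
              grid_step, coverage)
    )
  })
}

#' Gabriel-criteria LD blocks
#'
#' Classifies each SNP pair from its D' confidence interval: "strong LD"
#' when `ci_low >= ci_low_strong` and `ci_high >= ci_high_strong`; "strong
#' recombination" when `ci_high < ci_high_recomb`; anything else (or a
#' degenerate pair) is uninformative. A candidate interval of map-ordered
#' SNPs is a block when its outermost pair is in strong LD and the strong-LD
#' fraction of its informative pairs is at least `informative_frac`. Among
#' qualifying intervals, the longest (most SNPs spanned) non-overlapping
#' ones are selected greedily, leftmost first on ties.
#'
#' @param pairs Pairwise tibble from [ld_pairs()] (needs `snp_i`, `snp_j`,
#'   `ci_low`, `ci_high`).
#' @param snp_map Map tibble for the candidate SNPs of one chromosome
#'   (columns `id`, `chromosome`, `pos_cM`), in map order.
#' @param ci_low_strong,ci_high_strong,ci_high_recomb,informative_frac
#'   Gabriel thresholds; defaults 0.70, 0.98, 0.90, 0.95.
#' @return Tibble, one row per block: `chromosome`, `start_snp`, `end_snp`,
#'   `start_cM`, `end_cM`, `n_snps`, `n_strong_ld_pairs`,
#'   `n_informative_pairs`, and a list-column `members`.
#' @export
gabriel_blocks <- function(pairs, snp_map,
                           ci_low_strong = 0.70, ci_high_strong = 0.98,
                           ci_high_recomb = 0.90, informative_frac = 0.95) {
  ids <- snp_map$id
  m <- length(ids)
  if (length(unique(snp_map$chromosome)) > 1) {
    stop("gabriel_blocks operates on one chromosome at a time", call. = FALSE)
  }
  if (is.unsorted(snp_map$pos_cM)) {
    stop("snp_map must be in map order", call. = FALSE)
  }
  empty <- tibble::tibble(
    chromosome = integer(0), start_snp = character(0), end_snp = character(0),
    start_cM = numeric(0), end_cM = numeric(0), n_snps = integer(0),
    n_strong_ld_pairs = integer(0), n_informative_pairs = integer(0),
    members = list()
  )
  if (m < 2) return(empty)

  strong <- matrix(FALSE, m, m)
  recomb <- matrix(FALSE, m, m)
  ii <- match(pairs$snp_i, ids)
  jj <- match(pairs$snp_j, ids)
  ok <- !is.na(ii) & !is.na(jj) & !is.na(pairs$ci_low) & !is.na(pairs$ci_high)
  s <- ok & pairs$ci_low >= ci_low_strong & pairs$ci_high >= ci_high_strong
  r <- ok & pairs$ci_high < ci_high_recomb
  strong[cbind(ii[s], jj[s])] <- TRUE
  strong[cbind(jj[s], ii[s])] <- TRUE
  recomb[cbind(ii[r], jj[r])] <- TRUE
  recomb[cbind(jj[r], ii[r])] <- TRUE

  # all qualifying candidate intervals
  cand <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      if (!strong[i, j]) next
      sub <- i:j
      ns <- sum(strong[sub, sub][upper.tri(diag(length(sub)))])
      nr <- sum(recomb[sub, sub][upper.tri(diag(length(sub)))])
      ninf <- ns + nr
      if (ninf > 0 && ns / ninf >= informative_frac) {
        cand[[length(cand) + 1L]] <- c(i = i, j = j, ns = ns, ninf = ninf)
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # greedy: longest span first, leftmost on ties
  ord <- order(-(cand[, "j"] - cand[, "i"]), cand[, "i"])
  cand <- cand[ord, , drop = FALSE]
  taken <- rep(FALSE, m)
  blocks <- list()
  for (r_i in seq_len(nrow(cand))) {
    i <- cand[r_i, "i"]; j <- cand[r_i, "j"]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      chromosome = snp_map$chromosome[1],
      start_snp = ids[i], end_snp = ids[j],
      start_cM = snp_map$pos_cM[i], end_cM = snp_map$pos_cM[j],
      n_snps = as.integer(j - i + 1),
      n_strong_ld_pairs = as.integer(cand[r_i, "ns"]),
      n_informative_pairs = as.integer(cand[r_i, "ninf"]),
      members = list(ids[i:j])
    )
  }
  out <- dplyr::bind_rows(blocks)
  dplyr::arrange(out, .data$start_cM)
}
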