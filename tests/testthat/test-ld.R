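# genotypes for two loci from true haplotype frequencies (random mating)
sample_two_locus <- function(n, hap, seed) {
  set.seed(seed)
  gam <- function() sample(1:4, n, replace = TRUE, prob = hap)
  g1 <- gam(); g2 <- gam()
  a2i <- c(0L, 0L, 1L, 1L); a2j <- c(0L, 1L, 0L, 1L)
  list(gi = a2i[g1] + a2i[g2], gj = a2j[g1] + a2j[g2])
}

test_that("EM equals direct gamete counting when phase is unambiguous", {
  set.seed(21)
  for (rep in 1:20) {
    repeat {
      gi <- sample(0:2, 40, replace = TRUE)
      gj <- sample(0:2, 40, replace = TRUE)
      gj[gi == 1 & gj == 1] <- 0  # remove double heterozygotes
      if (length(unique(gi)) > 1 && length(unique(gj)) > 1) break
    }
    em <- em_haplotype_freq(gi, gj)
    expect_equal(em$hap, oracle_gamete_count(gi, gj), tolerance = 1e-10)
  }
})

test_that("EM handles complete LD, equilibrium and degenerate pairs", {
  g <- c(rep(0L, 150), rep(1L, 240), rep(2L, 110))
  em <- em_haplotype_freq(g, g)
  expect_equal(em$hap[["p12"]], 0, tolerance = 1e-6)
  expect_equal(em$hap[["p21"]], 0, tolerance = 1e-6)
  expect_equal(as.numeric(d_prime(em$hap)), 1, tolerance = 1e-9)

  # independent loci at p = q = 0.5: D within 3 SE of zero
  s <- sample_two_locus(10000, c(0.25, 0.25, 0.25, 0.25), seed = 22)
  emi <- em_haplotype_freq(s$gi, s$gj)
  D <- attr(d_prime(emi$hap), "D")
  expect_lt(abs(D), 3 * sqrt(0.25 * 0.75 / (2 * 10000)))

  dg <- em_haplotype_freq(rep(0L, 30), sample(0:2, 30, replace = TRUE))
  expect_true(dg$degenerate)
  expect_true(is.na(d_prime(dg$hap)))
})

test_that("EM log-likelihood never decreases across iterations", {
  set.seed(23)
  for (rep in 1:25) {
    hap <- as.numeric(stats::rgamma(4, 0.8) + 0.02)
    hap <- hap / sum(hap)
    s <- sample_two_locus(80, hap, seed = 2300 + rep)
    em <- em_haplotype_freq(s$gi, s$gj)
    if (em$degenerate || length(em$loglik_trace) < 2) next
    expect_true(all(diff(em$loglik_trace) > -1e-9))
  }
})

test_that("D-prime follows its normalisation formula", {
  expect_equal(as.numeric(d_prime(c(0.5, 0, 0, 0.5))), 1)
  expect_equal(as.numeric(d_prime(c(0.25, 0.25, 0.25, 0.25))), 0)
  dp <- d_prime(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(attr(dp, "D"), 0.15)
  expect_equal(attr(dp, "Dmax"), 0.25)
  expect_equal(as.numeric(dp), 0.6)

  # invariance to swapping allele labels at either locus and to locus swap
  set.seed(24)
  for (rep in 1:20) {
    h <- as.numeric(stats::rgamma(4, 1) + 0.05)
    h <- h / sum(h)
    base <- as.numeric(d_prime(h))
    swap_i <- as.numeric(d_prime(h[c(3, 4, 1, 2)]))
    swap_j <- as.numeric(d_prime(h[c(2, 1, 4, 3)]))
    swap_loci <- as.numeric(d_prime(h[c(1, 3, 2, 4)]))
    expect_equal(swap_i, base, tolerance = 1e-12)
    expect_equal(swap_j, base, tolerance = 1e-12)
    expect_equal(swap_loci, base, tolerance = 1e-12)
  }
})

test_that("LOD is zero at equilibrium estimates and large under complete LD", {
  # exactly factorised genotype table (Hardy-Weinberg at both loci, counts
  # proportional to the product of marginals): the EM fixed point is D = 0
  tab <- outer(c(4L, 8L, 4L), c(4L, 8L, 4L))
  gi <- rep(rep(0:2, each = 3), times = as.vector(t(tab)))
  gj <- rep(rep(0:2, times = 3), times = as.vector(t(tab)))
  em <- em_haplotype_freq(gi, gj)
  expect_equal(attr(d_prime(em$hap), "D"), 0, tolerance = 1e-12)
  expect_equal(lod_score(gi, gj), 0, tolerance = 1e-8)

  g <- c(rep(0L, 200), rep(1L, 150), rep(2L, 150))
  expect_gt(lod_score(g, g), 2)

  # independent loci: LOD concentrates near zero
  lods <- vapply(1:30, function(r) {
    s <- sample_two_locus(500, c(0.25, 0.25, 0.25, 0.25), seed = 3000 + r)
    lod_score(s$gi, s$gj)
  }, numeric(1))
  expect_lt(stats::median(lods), 0.5)
})

test_that("D-prime confidence intervals are calibrated at the extremes", {
  # complete LD at n = 500: upper bound hits 1, lower bound close to it
  hap1 <- c(0.6, 0, 0, 0.4)
  hits <- 0L
  for (r in 1:20) {
    s <- sample_two_locus(500, hap1, seed = 4000 + r)
    ci <- ld_confidence_interval(s$gi, s$gj)
    expect_equal(ci[["ci_high"]], 1.0)
    if (ci[["ci_low"]] >= 0.98) hits <- hits + 1L
  }
  expect_gte(hits, 18)

  # tiny uninformative samples must give wide intervals
  set.seed(25)
  widths <- vapply(1:10, function(r) {
    s <- sample_two_locus(10, c(0.3, 0.2, 0.25, 0.25), seed = 5000 + r)
    if (length(unique(s$gi)) < 2 || length(unique(s$gj)) < 2) return(NA_real_)
    ci <- ld_confidence_interval(s$gi, s$gj)
    ci[["ci_high"]] - ci[["ci_low"]]
  }, numeric(1))
  expect_gt(mean(widths, na.rm = TRUE), 0.5)
})

test_that("gabriel_blocks matches exhaustive interval enumeration", {
  # constructed 6-SNP panel: SNPs 1-4 copies of one pattern with 2% noise,
  # SNPs 5-6 independent
  set.seed(26)
  n <- 300
  base <- rbinom(n, 2, 0.4)
  flip <- function(x) { i <- runif(n) < 0.02; x[i] <- sample(0:2, sum(i), TRUE); x }
  g <- cbind(base, flip(base), flip(base), flip(base),
             rbinom(n, 2, 0.3), rbinom(n, 2, 0.45))
  colnames(g) <- sprintf("C1S%d", 1:6)
  map <- tibble::tibble(serial = 1:6, chromosome = 1L, index = 1:6,
                        id = colnames(g), pos_cM = (1:6) * 0.05)
  pairs <- ld_pairs(g)
  blocks <- gabriel_blocks(pairs, map)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$start_snp, "C1S1")
  expect_equal(blocks$end_snp, "C1S4")
  expect_equal(blocks$n_snps, 4L)

  # same answer as the brute-force oracle on the classification matrices
  strong <- recomb <- matrix(FALSE, 6, 6)
  ii <- match(pairs$snp_i, colnames(g)); jj <- match(pairs$snp_j, colnames(g))
  s <- !is.na(pairs$ci_low) & pairs$ci_low >= 0.7 & pairs$ci_high >= 0.98
  r <- !is.na(pairs$ci_high) & pairs$ci_high < 0.9
  strong[cbind(ii[s], jj[s])] <- strong[cbind(jj[s], ii[s])] <- TRUE
  recomb[cbind(ii[r], jj[r])] <- recomb[cbind(jj[r], ii[r])] <- TRUE
  oracle <- oracle_gabriel(strong, recomb)
  expect_equal(nrow(oracle), 1)
  expect_equal(unname(oracle[1, ]), c(1L, 4L))
})

test_that("gabriel_blocks on random classifications equals the oracle", {
  set.seed(27)
  for (rep in 1:40) {
    m <- sample(4:10, 1)
    ids <- sprintf("C1S%d", 1:m)
    map <- tibble::tibble(serial = 1:m, chromosome = 1L, index = 1:m,
                          id = ids, pos_cM = (1:m) * 0.05)
    combos <- utils::combn(m, 2)
    cls <- sample(c("strong", "recomb", "none"), ncol(combos), TRUE,
                  prob = c(0.5, 0.25, 0.25))
    pairs <- tibble::tibble(
      snp_i = ids[combos[1, ]], snp_j = ids[combos[2, ]],
      ci_low = ifelse(cls == "strong", 0.8, ifelse(cls == "recomb", 0.05, 0.5)),
      ci_high = ifelse(cls == "strong", 1.0, ifelse(cls == "recomb", 0.5, 0.95))
    )
    blocks <- gabriel_blocks(pairs, map)
    strong <- recomb <- matrix(FALSE, m, m)
    ij <- cbind(combos[1, ], combos[2, ])
    strong[ij[cls == "strong", , drop = FALSE]] <- TRUE
    recomb[ij[cls == "recomb", , drop = FALSE]] <- TRUE
    strong <- strong | t(strong); recomb <- recomb | t(recomb)
    oracle <- oracle_gabriel(strong, recomb)
    expect_equal(nrow(blocks), nrow(oracle))
    if (nrow(blocks)) {
      expect_equal(match(blocks$start_snp, ids), unname(oracle[, 1]))
      expect_equal(match(blocks$end_snp, ids), unname(oracle[, 2]))
      # blocks never overlap and members are contiguous
      spans <- Map(seq, match(blocks$start_snp, ids), match(blocks$end_snp, ids))
      expect_equal(anyDuplicated(unlist(spans)), 0L)
    }
  }
})

test_that("degenerate and trivial block topologies behave", {
  ids <- sprintf("C1S%d", 1:2)
  map2 <- tibble::tibble(serial = 1:2, chromosome = 1L, index = 1:2,
                         id = ids, pos_cM = c(0.05, 0.10))
  strong_pair <- tibble::tibble(snp_i = ids[1], snp_j = ids[2],
                                ci_low = 0.9, ci_high = 1.0)
  expect_equal(gabriel_blocks(strong_pair, map2)$n_snps, 2L)
  recomb_pair <- tibble::tibble(snp_i = ids[1], snp_j = ids[2],
                                ci_low = 0.05, ci_high = 0.5)
  expect_equal(nrow(gabriel_blocks(recomb_pair, map2)), 0)
})
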