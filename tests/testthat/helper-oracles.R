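# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: coancestry recursion instead of the
# tabular A matrix, dense-matrix REML/GLS instead of the spectral shortcuts,
# Henderson's equations instead of GLS, direct gamete counting instead of
# EM, and exhaustive interval enumeration instead of the greedy block scan.

# kinship (coancestry) by recursion on a parents-first pedigree
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  pos <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  f <- matrix(0, n, n)
  memo <- new.env()
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else if (i < j) {
      0.5 * (phi(i, si[j]) + phi(i, di[j]))
    } else {
      0.5 * (phi(j, si[i]) + phi(j, di[i]))
    }
    memo[[key]] <- val
    val
  }
  for (i in seq_len(n)) for (j in i:n) {
    f[i, j] <- f[j, i] <- phi(i, j)
  }
  dimnames(f) <- list(ped$id, ped$id)
  f
}

oracle_A <- function(ped) 2 * oracle_kinship(ped)

# random valid pedigree of n individuals (parents drawn among earlier ones)
random_pedigree <- function(n, p_founder = 0.4) {
  id <- sprintf("I%d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) > p_founder) {
      sire[i] <- id[sample.int(i - 1L, 1)]
      repeat {
        dam[i] <- id[sample.int(i - 1L, 1)]
        if (dam[i] != sire[i]) break
        if (i == 2L) break
      }
      if (dam[i] == sire[i]) { sire[i] <- NA; dam[i] <- NA }
    }
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam))
}

# full REML criterion by brute-force dense algebra, at given components
oracle_reml_loglik <- function(y, K, sigma_a2, sigma_e2) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- sigma_a2 * K + sigma_e2 * diag(n)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% crossprod(X, Vi)
  -0.5 * (determinant(V)$modulus + log(det(XtViX)) + drop(crossprod(y, P %*% y)) +
            (n - 1) * log(2 * pi))
}

# dense REML estimate over a lambda grid + optimize, fully via solve()
oracle_reml_fit <- function(y, K) {
  obj <- function(loglam) {
    lam <- exp(loglam)
    # profile sigma_e2 at this ratio by direct 1-D inner optimisation
    inner <- stats::optimize(function(s2e) {
      oracle_reml_loglik(y, K, lam * s2e, s2e)
    }, interval = c(1e-8, 1e4 * stats::var(y)), maximum = TRUE, tol = 1e-9)
    inner$objective
  }
  opt <- stats::optimize(obj, interval = log(c(1e-6, 1e3)),
                         maximum = TRUE, tol = 1e-7)
  lam <- exp(opt$maximum)
  s2e <- stats::optimize(function(s2e) oracle_reml_loglik(y, K, lam * s2e, s2e),
                         interval = c(1e-8, 1e4 * stats::var(y)),
                         maximum = TRUE, tol = 1e-10)$maximum
  list(lambda = lam, sigma_e2 = s2e, sigma_a2 = lam * s2e,
       loglik = opt$objective)
}

# generalised least squares by direct inversion
oracle_gls <- function(y, X, V) {
  Vi <- solve(V)
  C <- solve(crossprod(X, Vi %*% X))
  beta <- unname(drop(C %*% crossprod(X, Vi %*% y)))
  list(beta = beta, cov = unname(C))
}

# Henderson's mixed model equations for y = X beta + Z a + e,
# a ~ N(0, A sigma_a2), e ~ N(0, I sigma_e2); Z = incidence to all animals
oracle_mme <- function(y, X, Z, A, sigma_a2, sigma_e2) {
  lam <- sigma_e2 / sigma_a2
  Ainv <- solve(A)
  lhs <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + lam * Ainv)
  )
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(lhs, rhs)
  Ci <- solve(lhs)
  p <- ncol(X)
  list(beta = unname(sol[seq_len(p)]),
       cov_beta = unname(sigma_e2 * Ci[seq_len(p), seq_len(p), drop = FALSE]))
}

# two-locus haplotype counting when phase is unambiguous
oracle_gamete_count <- function(gi, gj) {
  stopifnot(!any(gi == 1 & gj == 1))
  c11 <- sum(2 * (gi == 0 & gj == 0)) + sum(gi == 0 & gj == 1) +
    sum(gi == 1 & gj == 0)
  c12 <- sum(2 * (gi == 0 & gj == 2)) + sum(gi == 0 & gj == 1) +
    sum(gi == 1 & gj == 2)
  c21 <- sum(2 * (gi == 2 & gj == 0)) + sum(gi == 1 & gj == 0) +
    sum(gi == 2 & gj == 1)
  c22 <- sum(2 * (gi == 2 & gj == 2)) + sum(gi == 2 & gj == 1) +
    sum(gi == 1 & gj == 2)
  tot <- c11 + c12 + c21 + c22
  c(p11 = c11, p12 = c12, p21 = c21, p22 = c22) / tot
}

# exhaustive Gabriel-block evaluation: all intervals, then the same greedy
# longest/leftmost selection applied to the full candidate list
oracle_gabriel <- function(strong, recomb, frac = 0.95) {
  m <- nrow(strong)
  cand <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (!strong[i, j]) next
    sub <- i:j
    ut <- upper.tri(matrix(0, length(sub), length(sub)))
    ns <- sum(strong[sub, sub][ut])
    nr <- sum(recomb[sub, sub][ut])
    if ((ns + nr) > 0 && ns / (ns + nr) >= frac) {
      cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  if (!length(cand)) return(matrix(integer(0), 0, 2))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand[, 2] - cand[, 1]), cand[, 1]), , drop = FALSE]
  taken <- rep(FALSE, m)
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    out[[length(out) + 1L]] <- c(i, j)
  }
  do.call(rbind, out[order(vapply(out, `[`, integer(1), 1))])
}

# small scaled-down simulation configs used by several test files
tiny_qtn <- function() {
  tibble::tibble(
    chromosome = 1L, snp_index = 25L, action = "additive", effect = 1,
    partner_snp = NA_integer_, phase_note = ""
  )
}

tiny_config <- function(seed, qtn = tiny_qtn(), ...) {
  sim_config(n_sires = 5, n_dams_per_sire = 4, n_progeny_per_dam = 6,
             n_phenotyped_per_dam = 4, n_chromosomes = 2,
             snps_per_chromosome = 60, qtn_spec = qtn, seed = seed, ...)
}

no_qtn <- function() {
  tibble::tibble(chromosome = integer(0), snp_index = integer(0),
                 action = character(0), effect = numeric(0),
                 partner_snp = integer(0), phase_note = character(0))
}

# phased genotypes built by hand for enumeration tests
manual_phased <- function(pat, mat, n_chr = 1L) {
  m <- ncol(pat)
  map <- tibble::tibble(serial = seq_len(m), chromosome = rep(1L, m),
                       index = seq_len(m),
                       id = sprintf("C1S%d", seq_len(m)),
                       pos_cM = seq_len(m) * 0.05)
  ids <- sprintf("I%d", seq_len(nrow(pat)))
  structure(list(ids = ids, map = map,
                 pat = `dimnames<-`(pat, list(ids, map$id)),
                 mat = `dimnames<-`(mat, list(ids, map$id))),
            class = "phased_geno")
}
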