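# small population with genuine family structure for REML exercises
reml_fixture <- function(seed, n_fam = 20, prog = 8, h2 = 0.4) {
  set.seed(seed)
  ped <- list()
  k <- 0
  id <- sire <- dam <- character(0)
  for (f in seq_len(n_fam)) {
    s <- sprintf("S%d", f); d <- sprintf("D%d", f)
    id <- c(id, s, d); sire <- c(sire, NA, NA); dam <- c(dam, NA, NA)
    for (p in seq_len(prog)) {
      id <- c(id, sprintf("P%d_%d", f, p)); sire <- c(sire, s); dam <- c(dam, d)
    }
  }
  ped <- as_pedigree(data.frame(id = id, sire = sire, dam = dam))
  A <- build_A(ped)
  n <- nrow(ped)
  sa2 <- h2; se2 <- 1 - h2
  L <- chol(A + diag(1e-8, n))
  a <- drop(crossprod(L, rnorm(n))) * sqrt(sa2)
  prog_ids <- ped$id[!is.na(ped$sire)]
  y <- 5 + a[match(prog_ids, ped$id)] + rnorm(length(prog_ids), 0, sqrt(se2))
  trait <- tibble::tibble(id = prog_ids, value = y)
  class(trait) <- c("trait_tbl", class(trait))
  list(ped = ped, A = A, trait = trait)
}

# compact scan fixture: family-structured population with genotypes
scan_fixture <- function(seed, n_fam = 10, prog = 6, m = 40, h2 = 0.3,
                         qtn_col = NULL, qtn_eff = 0) {
  set.seed(seed)
  id <- sire <- dam <- character(0)
  for (f in seq_len(n_fam)) {
    s <- sprintf("S%d", f); d <- sprintf("D%d", f)
    id <- c(id, s, d); sire <- c(sire, NA, NA); dam <- c(dam, NA, NA)
    for (p in seq_len(prog)) {
      id <- c(id, sprintf("P%d_%d", f, p)); sire <- c(sire, s); dam <- c(dam, d)
    }
  }
  ped <- as_pedigree(data.frame(id = id, sire = sire, dam = dam))
  n <- nrow(ped)
  A <- build_A(ped)
  # genotypes: founder alleles drawn per family, dropped one generation
  freq <- runif(m, 0.1, 0.5)
  g <- matrix(0L, n, m, dimnames = list(ped$id, sprintf("C1S%d", 1:m)))
  founder <- is.na(ped$sire)
  hap <- array(rbinom(2 * n * m, 1, rep(freq, each = 2 * n)), c(2, n, m))
  for (i in which(!founder)) {
    s <- match(ped$sire[i], ped$id); d <- match(ped$dam[i], ped$id)
    pick <- rbinom(m, 1, 0.5) + 1
    hap[1, i, ] <- hap[cbind(pick, s, 1:m)]
    pick <- rbinom(m, 1, 0.5) + 1
    hap[2, i, ] <- hap[cbind(pick, d, 1:m)]
  }
  g[] <- hap[1, , ] + hap[2, , ]
  sa2 <- h2; se2 <- 1 - h2
  L <- chol(A + diag(1e-8, n))
  a <- drop(crossprod(L, rnorm(n))) * sqrt(sa2)
  y_all <- 3 + a + rnorm(n, 0, sqrt(se2))
  if (!is.null(qtn_col)) y_all <- y_all + qtn_eff * g[, qtn_col]
  prog_ids <- ped$id[!founder]
  trait <- tibble::tibble(id = prog_ids, value = y_all[match(prog_ids, ped$id)])
  class(trait) <- c("trait_tbl", class(trait))
  map <- tibble::tibble(serial = 1:m, chromosome = 1L, index = 1:m,
                        id = colnames(g), pos_cM = (1:m) * 0.05)
  list(ped = ped, A = A, g = g, map = map, trait = trait)
}
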