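#' Simulate the two-generation half-sib pedigree
#'
#' Founder sires and dams are unrelated; each sire is mated to
#' `n_dams_per_sire` dams and each dam produces `n_progeny_per_dam` progeny.
#' Under the defaults (20 sires x 10 dams x 15 progeny) the pedigree holds
#' 3,220 individuals, 3,000 of them in the second generation.
#'
#' @param config A [sim_config()].
#' @return A `ped_tbl` tibble (ids `S*` for sires, `D*` for dams, `P*` for
#'   progeny), parents first.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$n_sires
  nd <- config$n_dams_per_sire
  np <- config$n_progeny_per_dam
  sires <- sprintf("S%d", seq_len(ns))
  dams  <- sprintf("D%d", seq_len(ns * nd))
  dam_sire <- sires[ceiling(seq_along(dams) / nd)]
  prog  <- sprintf("P%d", seq_len(ns * nd * np))
  prog_dam  <- dams[ceiling(seq_along(prog) / np)]
  prog_sire <- dam_sire[ceiling(seq_along(prog) / np)]
  as_pedigree(data.frame(
    id   = c(sires, dams, prog),
    sire = c(rep(NA, ns + ns * nd), prog_sire),
    dam  = c(rep(NA, ns + ns * nd), prog_dam)
  ))
}

#' Haldane map function
#'
#' Recombination probability between two loci separated by `d` Morgan under
#' the Haldane (no-interference) model: `0.5 * (1 - exp(-2 d))`.
#'
#' @param d Map distance in Morgan (vectorised, non-negative).
#' @return Recombination probabilities in `[0, 0.5)`.
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative", call. = FALSE)
  0.5 * (1 - exp(-2 * d))
}

new_phased_geno <- function(ids, map, pat, mat) {
  dimnames(pat) <- dimnames(mat) <- list(ids, map$id)
  structure(list(ids = ids, map = map, pat = pat, mat = mat),
            class = "phased_geno")
}

#' Simulate founder haplotypes as mosaics of ancestral templates
#'
#' Each founder haplotype is a mosaic over a pool of
#' `n_ancestral_haplotypes` ancestral templates: the template index follows a
#' Markov chain along the chromosome, switching between adjacent SNPs with
#' probability `1 - exp(-rate * d_cM)` and landing on a uniformly drawn
#' template. Ancestral allele frequencies are uniform per SNP, so a fraction
#' of SNPs is monomorphic in the pool (and more become monomorphic in the
#' finite founder sample), mimicking a marker panel that includes dead
#' markers. The mosaic structure creates linkage disequilibrium that decays
#' with map distance.
#'
#' Draws from the current RNG state; seed upstream for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A `phased_geno` object for the founders: allele matrices `pat` and
#'   `mat` (values 1/2, individuals x SNPs; the two founder haplotypes are
#'   labelled arbitrarily) and the SNP `map`.
#' @export
simulate_founder_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- sim_snp_map(config)
  n_founders <- config$n_sires + config$n_sires * config$n_dams_per_sire
  ids <- c(sprintf("S%d", seq_len(config$n_sires)),
           sprintf("D%d", seq_len(config$n_sires * config$n_dams_per_sire)))
  n_anc <- config$n_ancestral_haplotypes
  m <- config$snps_per_chromosome
  step_cM <- 100 * config$chromosome_length / m
  p_switch <- 1 - exp(-config$ancestral_switch_rate * step_cM)

  pat <- matrix(1L, n_founders, nrow(map))
  mat <- matrix(1L, n_founders, nrow(map))
  for (chr in seq_len(config$n_chromosomes)) {
    cols <- which(map$chromosome == chr)
    freq <- stats::runif(m)
    anc <- matrix(stats::rbinom(n_anc * m, 1L, rep(freq, each = n_anc)) + 1L,
                  nrow = n_anc)
    for (h in seq_len(2L * n_founders)) {
      if (m == 1L) {
        states <- sample.int(n_anc, 1L)
      } else {
        sw <- stats::rbinom(m - 1L, 1L, p_switch)
        seg <- cumsum(c(0L, sw)) + 1L
        seg_state <- sample.int(n_anc, max(seg), replace = TRUE)
        states <- seg_state[seg]
      }
      alleles <- anc[cbind(states, seq_len(m))]
      if (h <= n_founders) pat[h, cols] <- alleles
      else mat[h - n_founders, cols] <- alleles
    }
  }
  new_phased_geno(ids, map, pat, mat)
}

#' Drop genes through a pedigree
#'
#' Simulates genotype transmission: every non-founder receives one
#' recombinant gamete from its sire (stored as the paternal haplotype) and
#' one from its dam (maternal haplotype). Crossovers between adjacent SNPs
#' occur independently with the Haldane probability
#' `0.5 (1 - exp(-2 d))` for map distance `d` Morgan, and each gamete starts
#' on a uniformly chosen parental haplotype.
#'
#' Draws from the current RNG state.
#'
#' @param pedigree A `ped_tbl`; every non-founder's parents must both be
#'   present among the founder haplotypes or earlier generations.
#' @param founder_haplotypes A `phased_geno` covering all pedigree founders.
#' @return A `phased_geno` over all pedigree members, parental origin
#'   recorded in the `pat`/`mat` slots.
#' @export
drop_genes <- function(pedigree, founder_haplotypes) {
  stopifnot(inherits(pedigree, "ped_tbl"), inherits(founder_haplotypes, "phased_geno"))
  fh <- founder_haplotypes
  map <- fh$map
  m_all <- nrow(map)
  n <- nrow(pedigree)
  is_founder <- is.na(pedigree$sire) & is.na(pedigree$dam)
  half_founder <- xor(is.na(pedigree$sire), is.na(pedigree$dam))
  if (any(half_founder)) {
    stop("non-founder with a single known parent cannot be gene-dropped: ",
         paste(pedigree$id[half_founder][1], "..."), call. = FALSE)
  }
  if (!all(pedigree$id[is_founder] %in% fh$ids)) {
    stop("founder(s) missing from founder_haplotypes: ",
         paste(setdiff(pedigree$id[is_founder], fh$ids)[1], "..."), call. = FALSE)
  }

  # per-chromosome blocks, SNPs x individuals: gametes are contiguous
  # columns, which keeps the segment copies of meiosis cache-friendly
  chr_cols <- split(seq_len(m_all), map$chromosome)
  fidx <- match(fh$ids, pedigree$id)
  pat_blk <- lapply(chr_cols, function(cols) {
    b <- matrix(1L, length(cols), n)
    b[, fidx[!is.na(fidx)]] <- t(fh$pat[!is.na(fidx), cols, drop = FALSE])
    b
  })
  mat_blk <- lapply(chr_cols, function(cols) {
    b <- matrix(1L, length(cols), n)
    b[, fidx[!is.na(fidx)]] <- t(fh$mat[!is.na(fidx), cols, drop = FALSE])
    b
  })
  rec_by_chr <- lapply(chr_cols, function(cols) {
    if (length(cols) < 2L) return(numeric(0))
    haldane(diff(map$pos_cM[cols]) / 100)
  })

  gens <- sort(unique(pedigree$generation[!is_founder]))
  for (g in gens) {
    rows <- which(pedigree$generation == g & !is_founder)
    si <- match(pedigree$sire[rows], pedigree$id)
    di <- match(pedigree$dam[rows], pedigree$id)
    for (k in seq_along(chr_cols)) {
      rec <- rec_by_chr[[k]]
      gp <- meiosis_batch(pat_blk[[k]][, si, drop = FALSE],
                          mat_blk[[k]][, si, drop = FALSE], rec)
      gm <- meiosis_batch(pat_blk[[k]][, di, drop = FALSE],
                          mat_blk[[k]][, di, drop = FALSE], rec)
      pat_blk[[k]][, rows] <- gp
      mat_blk[[k]][, rows] <- gm
    }
  }
  new_phased_geno(pedigree$id, map, t(do.call(rbind, pat_blk)),
                  t(do.call(rbind, mat_blk)))
}

# One gamete per column of hapA/hapB (SNPs x gametes). Crossover events
# are sparse (about one per Morgan per gamete), so they are sampled per
# interval (Binomial count, then which gametes) instead of drawing a dense
# indicator matrix.
meiosis_batch <- function(hapA, hapB, rec_prob) {
  m <- nrow(hapA)
  g <- ncol(hapA)
  start <- stats::rbinom(g, 1L, 0.5)
  ev_gam <- integer(0)
  ev_int <- integer(0)
  if (m > 1L) {
    n_j <- stats::rbinom(length(rec_prob), g, rec_prob)
    idx_j <- which(n_j > 0L)
    if (length(idx_j)) {
      ev_gam <- unlist(lapply(idx_j, function(j) sample.int(g, n_j[j])),
                       use.names = FALSE)
      ev_int <- rep.int(idx_j, n_j[idx_j])
    }
  }
  has_x <- unique(ev_gam)
  no_x <- setdiff(seq_len(g), has_x)
  a0 <- no_x[start[no_x] == 0L]
  b0 <- no_x[start[no_x] == 1L]
  gam <- matrix(0L, m, g)
  if (length(a0)) gam[, a0] <- hapA[, a0, drop = FALSE]
  if (length(b0)) gam[, b0] <- hapB[, b0, drop = FALSE]
  if (length(ev_gam)) {
    splits <- split(ev_int, ev_gam)
    for (nm in names(splits)) {
      gi <- as.integer(nm)
      cuts <- c(0L, sort(splits[[nm]]), m)
      s <- start[gi]
      for (k in seq_len(length(cuts) - 1L)) {
        rng <- (cuts[k] + 1L):cuts[k + 1L]
        gam[rng, gi] <- if (s == 0L) hapA[rng, gi] else hapB[rng, gi]
        s <- 1L - s
      }
    }
  }
  gam
}

#' Collapse phased haplotypes to 0/1/2 genotype codes
#'
#' @param phased A `phased_geno`.
#' @return An integer matrix, individuals x SNPs, each entry the count of
#'   allele 2.
#' @export
phased_to_genotypes <- function(phased) {
  stopifnot(inherits(phased, "phased_geno"))
  g <- phased$pat + phased$mat - 2L  # alleles coded 1/2
  g
}

#' Genetic values from the QTN architecture
#'
#' Additive QTN contribute `effect * (count of allele 2)`; paternally
#' expressed imprinted QTN contribute `effect` only when allele 2 sits on
#' the paternally inherited haplotype; an epistatic pair contributes
#' `effect` only when the individual carries at least one copy of allele 2
#' at both partner loci. Contributions sum over QTN.
#'
#' @param phased A `phased_geno` for all individuals.
#' @param qtn_spec A QTN tibble as in [qtn_default_spec()].
#' @return Named numeric vector of genetic values, one per individual.
#' @export
assign_genetic_values <- function(phased, qtn_spec) {
  stopifnot(inherits(phased, "phased_geno"))
  map <- phased$map
  qtn_spec <- validate_qtn_spec(qtn_spec, max(map$chromosome),
                                max(map$index))
  col_of <- function(chr, idx) {
    j <- which(map$chromosome == chr & map$index == idx)
    if (length(j) != 1L) {
      stop("QTN points at a non-existent SNP: chromosome ", chr,
           " index ", idx, call. = FALSE)
    }
    j
  }
  g <- stats::setNames(numeric(length(phased$ids)), phased$ids)
  for (r in seq_len(nrow(qtn_spec))) {
    chr <- qtn_spec$chromosome[r]
    j <- col_of(chr, qtn_spec$snp_index[r])
    eff <- qtn_spec$effect[r]
    act <- qtn_spec$action[r]
    if (act == "additive") {
      g <- g + eff * ((phased$pat[, j] == 2L) + (phased$mat[, j] == 2L))
    } else if (act == "imprinted_paternal") {
      g <- g + eff * (phased$pat[, j] == 2L)
    } else { # epistatic_pair
      jp <- col_of(chr, qtn_spec$partner_snp[r])
      has_i <- (phased$pat[, j] == 2L) | (phased$mat[, j] == 2L)
      has_j <- (phased$pat[, jp] == 2L) | (phased$mat[, jp] == 2L)
      g <- g + eff * (has_i & has_j)
    }
  }
  g
}

#' Simulate phenotypes with a calibrated heritability
#'
#' The phenotype of a recorded individual is
#' `overall_mean + QTN genetic value + polygenic value + residual`.
#' Polygenic values follow the standard additive infinitesimal model:
#' founders are `N(0, sigma_poly^2)`, and each offspring receives the
#' midparent value plus a Mendelian-sampling deviation
#' `N(0, sigma_poly^2 / 2)` (parents are non-inbred in this design).
#' Variances are solved from the empirical QTN variance `V_q` so that the
#' total genetic variance is `V_q / (1 - polygenic_fraction)` and the ratio
#' of genetic to total variance equals `target_h2`; when the architecture
#' has no QTN variance the polygenic variance is fixed at 1 trait unit
#' squared and the residual is scaled to the same heritability.
#'
#' Exactly `n_phenotyped_per_dam` progeny per dam are recorded, chosen
#' uniformly at random; parents carry no phenotype.
#'
#' @param pedigree A `ped_tbl` from [simulate_pedigree()].
#' @param genetic_values Named vector from [assign_genetic_values()].
#' @param config A [sim_config()].
#' @return A tibble of class `trait_tbl` with columns `id`, `value`;
#'   attributes `sigma_poly2`, `sigma_e2`, `sigma_g2`, `qtn_var` record the
#'   calibration.
#' @export
simulate_phenotypes <- function(pedigree, genetic_values, config) {
  stopifnot(inherits(pedigree, "ped_tbl"), inherits(config, "sim_config"))
  if (!(config$target_h2 > 0 && config$target_h2 < 1)) {
    stop("target_h2 must lie strictly inside (0, 1)", call. = FALSE)
  }
  g <- genetic_values[pedigree$id]
  if (anyNA(g)) stop("genetic values missing for some pedigree members", call. = FALSE)

  vq <- stats::var(g)
  f <- config$polygenic_fraction
  if (vq > 0) {
    sigma_g2 <- vq / (1 - f)
    sigma_p2 <- sigma_g2 - vq
  } else {
    sigma_p2 <- 1
    sigma_g2 <- vq + sigma_p2
  }
  h2 <- config$target_h2
  sigma_e2 <- sigma_g2 * (1 - h2) / h2

  # polygenic gene-flow down the (already ordered) pedigree
  n <- nrow(pedigree)
  pos <- stats::setNames(seq_len(n), pedigree$id)
  a <- numeric(n)
  sd_f <- sqrt(sigma_p2)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (is.na(s) && is.na(d)) {
      a[i] <- stats::rnorm(1, 0, sd_f)
    } else {
      a[i] <- 0.5 * ((if (!is.na(s)) a[pos[s]] else 0) +
                     (if (!is.na(d)) a[pos[d]] else 0)) +
        stats::rnorm(1, 0, sqrt(sigma_p2 / 2))
    }
  }

  is_prog <- !is.na(pedigree$dam)
  prog <- pedigree$id[is_prog]
  by_dam <- split(prog, pedigree$dam[is_prog])
  phen_ids <- unlist(lapply(by_dam, function(ids) {
    sample(ids, min(config$n_phenotyped_per_dam, length(ids)))
  }), use.names = FALSE)
  phen_ids <- pedigree$id[pedigree$id %in% phen_ids]  # pedigree order

  idx <- pos[phen_ids]
  value <- config$overall_mean + g[idx] + a[idx] +
    stats::rnorm(length(idx), 0, sqrt(sigma_e2))
  out <- tibble::tibble(id = phen_ids, value = unname(value))
  class(out) <- c("trait_tbl", class(out))
  attr(out, "sigma_poly2") <- sigma_p2
  attr(out, "sigma_e2") <- sigma_e2
  attr(out, "sigma_g2") <- sigma_g2
  attr(out, "qtn_var") <- vq
  out
}

#' Simulate a complete study population
#'
#' Runs the full generator: pedigree, mosaic founder haplotypes, gene
#' dropping, QTN genetic values, and phenotypes for the recorded progeny.
#' All randomness flows from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_population` with elements `config`,
#'   `pedigree`, `phased`, `genotypes` (0/1/2 matrix, all individuals),
#'   `map`, `phenotypes`, `genetic_values`, `qtn_truth`.
#' @examples
#' pop <- simulate_population(sim_config(
#'   n_sires = 2, n_dams_per_sire = 2, n_progeny_per_dam = 3,
#'   n_phenotyped_per_dam = 2, snps_per_chromosome = 50, seed = 7
#' ))
#' dim(pop$genotypes)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pedigree <- simulate_pedigree(config)
  founders <- simulate_founder_haplotypes(config)
  phased <- drop_genes(pedigree, founders)
  genetic_values <- assign_genetic_values(phased, config$qtn_spec)
  phenotypes <- simulate_phenotypes(pedigree, genetic_values, config)
  structure(list(
    config = config,
    pedigree = pedigree,
    phased = phased,
    genotypes = phased_to_genotypes(phased),
    map = phased$map,
    phenotypes = phenotypes,
    genetic_values = genetic_values,
    qtn_truth = config$qtn_spec
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated half-sib population\n")
  cat("  individuals:", nrow(x$pedigree),
      "(", sum(is.na(x$pedigree$sire)), "founders )\n")
  cat("  SNPs:", nrow(x$map), "on", max(x$map$chromosome), "chromosomes\n")
  cat("  phenotyped:", nrow(x$phenotypes), "\n")
  cat("  QTN:", nrow(x$qtn_truth), "\n")
  invisible(x)
}
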