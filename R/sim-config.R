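#' Default QTN architecture for the simulated trait
#'
#' Seven quantitative trait nucleotides across five chromosomes: one
#' large-effect additive QTN on chromosome 1; two additive QTN in coupling
#' phase on chromosome 2; two additive QTN in repulsion phase on chromosome 3
#' (trait-increasing alleles on opposite haplotype backgrounds, encoded as
#' effects of opposite sign); one paternally expressed imprinted QTN on
#' chromosome 4; and one epistatic pair on chromosome 5 whose effect requires
#' at least one copy of allele 2 at both partner loci.
#'
#' Effect sizes are in trait units per the action's contrast. Under the
#' default population design and heritability, the chromosome 1 QTN explains
#' roughly 8-10% of the phenotypic variance and each remaining QTN roughly
#' 2-4%.
#'
#' @return A tibble with columns `chromosome`, `snp_index`, `action`,
#'   `effect`, `partner_snp`, `phase_note`.
#' @export
qtn_default_spec <- function() {
  tibble::tibble(
    chromosome  = c(1L, 2L, 2L, 3L, 3L, 4L, 5L),
    snp_index   = c(57L, 1640L, 1877L, 103L, 303L, 999L, 500L),
    action      = c("additive", "additive", "additive", "additive",
                    "additive", "imprinted_paternal", "epistatic_pair"),
    effect      = c(1.0, 0.5, 0.5, 0.5, -0.5, 0.6, 0.8),
    partner_snp = c(NA_integer_, NA, NA, NA, NA, NA, 1500L),
    phase_note  = c("large additive", "coupling", "coupling",
                    "repulsion", "repulsion", "", "")
  )
}

#' Simulation configuration
#'
#' Parameters of the two-generation half-sib population design: unrelated
#' founders (sires and dams), each sire mated to a fixed number of dams, each
#' dam producing a fixed number of progeny of which a subset is phenotyped.
#' Founder chromosomes are mosaics of a small pool of ancestral haplotypes,
#' which creates long-range linkage disequilibrium and a realistic fraction
#' of monomorphic markers; gametes are dropped through the pedigree with
#' recombination under the Haldane map function.
#'
#' @param n_sires Number of founder sires (default 20).
#' @param n_dams_per_sire Dams mated to each sire (default 10).
#' @param n_progeny_per_dam Progeny per dam (default 15).
#' @param n_phenotyped_per_dam Progeny per dam with a phenotype record
#'   (default 10), chosen uniformly at random.
#' @param n_chromosomes Number of chromosomes (default 5).
#' @param snps_per_chromosome Evenly spaced SNPs per chromosome
#'   (default 1998).
#' @param chromosome_length Chromosome length in Morgan (default 1.0). SNP k
#'   sits at `k * chromosome_length / snps_per_chromosome` Morgan.
#' @param qtn_spec QTN architecture tibble (see [qtn_default_spec()]).
#' @param target_h2 Broad-sense heritability targeted by the variance
#'   calibration, strictly inside (0, 1) (default 0.30).
#' @param polygenic_fraction Fraction of the total genetic variance assigned
#'   to the residual polygenic term rather than the explicit QTN
#'   (default 0.3).
#' @param n_ancestral_haplotypes Size of the ancestral haplotype pool
#'   (default 10).
#' @param ancestral_switch_rate Per-cM probability rate of switching
#'   ancestral template along a founder haplotype (default 0.05, i.e. mosaic
#'   segments of ~20 cM on average).
#' @param overall_mean Trait mean in trait units (default 10).
#' @param seed Integer seed driving every random draw of the simulation.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_sires * cfg$n_dams_per_sire # 200 dams
#' @export
sim_config <- function(n_sires = 20L,
                       n_dams_per_sire = 10L,
                       n_progeny_per_dam = 15L,
                       n_phenotyped_per_dam = 10L,
                       n_chromosomes = 5L,
                       snps_per_chromosome = 1998L,
                       chromosome_length = 1.0,
                       qtn_spec = qtn_default_spec(),
                       target_h2 = 0.30,
                       polygenic_fraction = 0.3,
                       n_ancestral_haplotypes = 10L,
                       ancestral_switch_rate = 0.05,
                       overall_mean = 10,
                       seed = 1L) {
  counts <- c(n_sires = n_sires, n_dams_per_sire = n_dams_per_sire,
              n_progeny_per_dam = n_progeny_per_dam,
              n_phenotyped_per_dam = n_phenotyped_per_dam,
              n_chromosomes = n_chromosomes,
              snps_per_chromosome = snps_per_chromosome,
              n_ancestral_haplotypes = n_ancestral_haplotypes)
  if (any(counts < 1)) {
    stop("all design counts must be positive: ",
         paste(names(counts)[counts < 1], collapse = ", "), call. = FALSE)
  }
  if (n_phenotyped_per_dam > n_progeny_per_dam) {
    stop("n_phenotyped_per_dam cannot exceed n_progeny_per_dam", call. = FALSE)
  }
  if (!(target_h2 > 0 && target_h2 < 1)) {
    stop("target_h2 must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!(polygenic_fraction >= 0 && polygenic_fraction < 1)) {
    stop("polygenic_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (chromosome_length <= 0 || ancestral_switch_rate < 0) {
    stop("chromosome_length must be positive and ancestral_switch_rate non-negative",
         call. = FALSE)
  }
  qtn_spec <- validate_qtn_spec(qtn_spec, n_chromosomes, snps_per_chromosome)
  structure(list(
    n_sires = as.integer(n_sires),
    n_dams_per_sire = as.integer(n_dams_per_sire),
    n_progeny_per_dam = as.integer(n_progeny_per_dam),
    n_phenotyped_per_dam = as.integer(n_phenotyped_per_dam),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length = chromosome_length,
    qtn_spec = qtn_spec,
    target_h2 = target_h2,
    polygenic_fraction = polygenic_fraction,
    n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
    ancestral_switch_rate = ancestral_switch_rate,
    overall_mean = overall_mean,
    seed = as.integer(seed)
  ), class = "sim_config")
}

validate_qtn_spec <- function(qtn, n_chr, m_chr) {
  qtn <- tibble::as_tibble(qtn)
  needed <- c("chromosome", "snp_index", "action", "effect")
  if (!all(needed %in% names(qtn))) {
    stop("qtn_spec needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!"partner_snp" %in% names(qtn)) qtn$partner_snp <- NA_integer_
  if (!"phase_note" %in% names(qtn)) qtn$phase_note <- ""
  ok_action <- qtn$action %in% c("additive", "imprinted_paternal", "epistatic_pair")
  if (!all(ok_action)) {
    stop("unknown QTN action: ", paste(unique(qtn$action[!ok_action]),
                                       collapse = ", "), call. = FALSE)
  }
  if (any(qtn$chromosome < 1 | qtn$chromosome > n_chr)) {
    stop("QTN chromosome outside 1..", n_chr, call. = FALSE)
  }
  idx <- c(qtn$snp_index, stats::na.omit(qtn$partner_snp))
  if (any(idx < 1 | idx > m_chr)) {
    stop("QTN snp_index outside 1..", m_chr, call. = FALSE)
  }
  is_epi <- qtn$action == "epistatic_pair"
  if (any(is_epi & is.na(qtn$partner_snp))) {
    stop("epistatic_pair QTN requires partner_snp", call. = FALSE)
  }
  if (any(!is_epi & !is.na(qtn$partner_snp))) {
    stop("partner_snp only allowed for epistatic_pair QTN", call. = FALSE)
  }
  qtn
}

#' SNP map implied by a simulation configuration
#'
#' SNP k on each chromosome is placed at
#' `k * chromosome_length / snps_per_chromosome` Morgan; ids are
#' `C<chromosome>S<index>` and a global serial number runs across
#' chromosomes in map order.
#'
#' @param config A `sim_config`.
#' @return A tibble with columns `serial`, `chromosome`, `index`, `id`,
#'   `pos_cM`.
#' @export
sim_snp_map <- function(config) {
  m <- config$snps_per_chromosome
  step_cM <- 100 * config$chromosome_length / m
  purrr::map_dfr(seq_len(config$n_chromosomes), function(chr) {
    tibble::tibble(
      chromosome = chr,
      index = seq_len(m),
      id = sprintf("C%dS%d", chr, seq_len(m)),
      pos_cM = seq_len(m) * step_cM
    )
  }) |>
    dplyr::mutate(serial = dplyr::row_number(), .before = 1)
}
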