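test_that("pedigree counts match the two-generation design", {
  cfg <- sim_config(seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 3220)
  expect_equal(sum(!is.na(ped$sire)), 3000)
  expect_equal(sum(ped$generation == 0), 220)

  tiny <- simulate_pedigree(sim_config(n_sires = 1, n_dams_per_sire = 1,
                                       n_progeny_per_dam = 1,
                                       n_phenotyped_per_dam = 1,
                                       qtn_spec = no_qtn(), seed = 1))
  expect_equal(nrow(tiny), 3)
  expect_equal(tiny$sire[3], "S1")
  expect_equal(tiny$dam[3], "D1")
})

test_that("every progeny's sire is its dam's assigned mate", {
  ped <- simulate_pedigree(sim_config(seed = 2))
  prog <- ped[!is.na(ped$sire), ]
  # exhaustive scan: each dam maps to exactly one sire, shared by all her progeny
  mate_of <- tapply(prog$sire, prog$dam, unique)
  expect_true(all(lengths(mate_of) == 1))
  # and the dam-to-sire assignment follows the nested design
  expect_equal(sum(lengths(tapply(prog$dam, prog$sire, unique))), 200)
})

test_that("founder haplotype edge cases behave as designed", {
  # one ancestral template: every founder identical, all SNPs monomorphic
  cfg1 <- tiny_config(seed = 3, n_ancestral_haplotypes = 1)
  set.seed(cfg1$seed)
  fh <- simulate_founder_haplotypes(cfg1)
  expect_equal(nrow(unique(rbind(fh$pat, fh$mat))), 1)
  g <- phased_to_genotypes(fh)
  expect_true(all(minor_allele_frequency(g) == 0))

  # zero switch rate: each haplotype is exactly one ancestral template
  cfg0 <- tiny_config(seed = 4, ancestral_switch_rate = 0,
                      n_ancestral_haplotypes = 4)
  set.seed(cfg0$seed)
  fh0 <- simulate_founder_haplotypes(cfg0)
  all_haps <- rbind(fh0$pat, fh0$mat)
  for (chr in 1:2) {
    cols <- fh0$map$chromosome == chr
    expect_lte(nrow(unique(all_haps[, cols])), 4)
  }
})

test_that("LD decays with map distance in founder haplotypes", {
  cfg <- sim_config(n_sires = 40, n_dams_per_sire = 2, n_progeny_per_dam = 1,
                    n_phenotyped_per_dam = 1, n_chromosomes = 1,
                    snps_per_chromosome = 1998, qtn_spec = no_qtn(), seed = 11)
  set.seed(cfg$seed)
  fh <- simulate_founder_haplotypes(cfg)
  g <- phased_to_genotypes(fh)
  maf <- minor_allele_frequency(g)
  poly <- which(maf >= 0.05)

  dprime_at_gap <- function(gap, n_pairs) {
    starts <- sample(poly[poly + gap <= max(poly)], n_pairs, replace = TRUE)
    vals <- vapply(starts, function(i) {
      j <- i + gap
      if (!(j %in% poly)) return(NA_real_)
      as.numeric(d_prime(em_haplotype_freq(g[, i], g[, j])$hap))
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  set.seed(99)
  near <- dprime_at_gap(1, 150)     # adjacent SNPs (0.05 cM)
  far <- dprime_at_gap(1000, 150)   # ~50 cM apart
  expect_gt(near, far)
})

test_that("gene dropping respects the map: linked loci co-segregate", {
  # two SNPs at 0 cM distance never recombine; crossover frequency at
  # 0.1 Morgan matches the Haldane closed form within 3 SE
  expect_equal(haldane(0), 0)
  expect_equal(haldane(0.1), 0.5 * (1 - exp(-0.2)))
  expect_lt(abs(haldane(1e6) - 0.5), 1e-12)
  expect_error(haldane(-1), "non-negative")

  n_meiosis <- 30000
  r_true <- haldane(0.1)
  # heterozygous parent phased 1-1 / 2-2 at two SNPs 10 cM apart:
  # a recombinant gamete is visible as alleles from different haplotypes
  hapA <- matrix(1L, 2, n_meiosis)
  hapB <- matrix(2L, 2, n_meiosis)
  set.seed(5)
  gam <- mmragwas:::meiosis_batch(hapA, hapB, rec_prob = r_true)
  rec_obs <- mean(gam[1, ] != gam[2, ])
  se <- sqrt(r_true * (1 - r_true) / n_meiosis)
  expect_lt(abs(rec_obs - r_true), 3 * se)

  gam0 <- mmragwas:::meiosis_batch(hapA, hapB, rec_prob = 0)
  expect_true(all(gam0[1, ] == gam0[2, ]))
})

test_that("gene dropping is Mendelian-consistent and phase-consistent", {
  cfg <- tiny_config(seed = 6)
  pop <- simulate_population(cfg)
  g <- pop$genotypes
  ped <- pop$pedigree

  expect_equal(g, (pop$phased$pat == 2L) + (pop$phased$mat == 2L),
               ignore_attr = FALSE)

  prog <- which(!is.na(ped$sire))
  for (i in prog) {
    s <- match(ped$sire[i], ped$id)
    d <- match(ped$dam[i], ped$id)
    gmin <- (g[s, ] == 2) + (g[d, ] == 2)
    gmax <- (g[s, ] >= 1) + (g[d, ] >= 1)
    expect_true(all(g[i, ] >= gmin & g[i, ] <= gmax))
    # paternal haplotype must be drawable from the sire's two haplotypes
    pat_ok <- pop$phased$pat[i, ] == pop$phased$pat[s, ] |
      pop$phased$pat[i, ] == pop$phased$mat[s, ]
    expect_true(all(pat_ok))
  }

  expect_error(
    drop_genes(as_pedigree(data.frame(id = c("A", "B", "C"),
                                      sire = c(NA, NA, "A"),
                                      dam = c(NA, NA, "B"))),
               simulate_founder_haplotypes(tiny_config(seed = 1))),
    "missing from founder_haplotypes")
})

test_that("genetic values follow the QTN action definitions", {
  # all-homozygous-11 individual scores zero; additive doses scale linearly
  qtn <- tibble::tibble(chromosome = 1L, snp_index = 2L, action = "additive",
                        effect = 2, partner_snp = NA_integer_, phase_note = "")
  ph <- manual_phased(pat = rbind(c(1L, 1L, 1L), c(1L, 2L, 1L), c(1L, 2L, 1L)),
                      mat = rbind(c(1L, 1L, 1L), c(1L, 1L, 1L), c(1L, 2L, 1L)))
  gv <- assign_genetic_values(ph, qtn)
  expect_equal(unname(gv), c(0, 2, 4))

  # imprinted QTN: all four phased heterozygote/homozygote configurations
  qtn_imp <- tibble::tibble(chromosome = 1L, snp_index = 1L,
                            action = "imprinted_paternal", effect = 1.5,
                            partner_snp = NA_integer_, phase_note = "")
  ph_imp <- manual_phased(pat = cbind(c(1L, 2L, 1L, 2L)),
                          mat = cbind(c(1L, 1L, 2L, 2L)))
  expect_equal(unname(assign_genetic_values(ph_imp, qtn_imp)),
               c(0, 1.5, 0, 1.5))

  # epistatic pair: effect requires allele 2 at both loci
  qtn_epi <- tibble::tibble(chromosome = 1L, snp_index = 1L,
                            action = "epistatic_pair", effect = 3,
                            partner_snp = 2L, phase_note = "")
  ph_epi <- manual_phased(
    pat = rbind(c(2L, 1L), c(2L, 2L), c(1L, 2L), c(1L, 1L)),
    mat = rbind(c(1L, 1L), c(1L, 1L), c(1L, 2L), c(1L, 1L))
  )
  expect_equal(unname(assign_genetic_values(ph_epi, qtn_epi)), c(0, 3, 0, 0))

  expect_error(validate_qtn <- assign_genetic_values(
    ph, tibble::tibble(chromosome = 1L, snp_index = 1L,
                       action = "epistatic_pair", effect = 1,
                       partner_snp = NA_integer_, phase_note = "")),
    "partner")
})

test_that("phenotype records match the design and calibration", {
  cfg <- tiny_config(seed = 8)
  pop <- simulate_population(cfg)
  tr <- pop$phenotypes
  # n_phenotyped_per_dam per dam, parents unphenotyped
  expect_equal(nrow(tr), 5 * 4 * 4)
  ped <- pop$pedigree
  expect_true(all(!is.na(ped$sire[match(tr$id, ped$id)])))
  dam_of <- ped$dam[match(tr$id, ped$id)]
  expect_true(all(table(dam_of) == 4))

  # near-degenerate residual: phenotype - mean approaches the QTN value
  cfg0 <- tiny_config(seed = 9, target_h2 = 0.9999, polygenic_fraction = 0)
  pop0 <- simulate_population(cfg0)
  gv <- pop0$genetic_values[pop0$phenotypes$id]
  expect_lt(max(abs(pop0$phenotypes$value - cfg0$overall_mean - gv)),
            0.1 * stats::sd(gv))

  expect_error(sim_config(target_h2 = 1), "target_h2")
  expect_error(sim_config(target_h2 = 0), "target_h2")
})

test_that("full default-scale structural counts are reproduced", {
  cfg <- sim_config(seed = 20)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$pedigree), 3220)
  expect_equal(ncol(pop$genotypes), 9990)
  expect_equal(nrow(pop$phenotypes), 2000)
  keep <- union(pop$pedigree$id[pop$pedigree$generation == 0],
                pop$phenotypes$id)
  expect_equal(nrow(restrict_individuals(pop$genotypes, keep)), 2220)
  # a realistic fraction of markers is monomorphic on the analysis set
  qc <- filter_snps(restrict_individuals(pop$genotypes, keep), pop$map)
  expect_gt(qc$report$n_monomorphic, 0)
})
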