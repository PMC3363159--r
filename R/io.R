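#' Write / read a genotype matrix as native TSV
#'
#' Individuals x SNPs small-integer codes with an `id` first column and SNP
#' ids as header; the primary interchange format of the package.
#'
#' @param genotypes Genotype matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = NA)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- as.character(df$id)
  if (any(!g %in% 0:2)) stop("genotype codes must be 0/1/2", call. = FALSE)
  g
}

#' Write phenotypes / QTN truth as TSV
#'
#' @param trait A `trait_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(trait, path) {
  utils::write.table(as.data.frame(trait[, c("id", "value")]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  out <- tibble::tibble(id = df$id, value = df$value)
  class(out) <- c("trait_tbl", class(out))
  out
}

#' @param qtn_truth QTN tibble as in [qtn_default_spec()].
#' @rdname write_phenotypes
#' @export
write_qtn_truth <- function(qtn_truth, path) {
  utils::write.table(as.data.frame(qtn_truth), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Write genotypes in PLINK text format
#'
#' `.ped`: family id (fixed `F0`), individual id, sire, dam, sex (0),
#' phenotype (-9), then two allele columns per SNP coded 1/2. `.map`:
#' chromosome, SNP id, cM position, and the within-chromosome index in the
#' base-pair column.
#'
#' @param genotypes Genotype matrix (codes 0/1/2, count of allele 2).
#' @param snp_map Map tibble (`chromosome`, `index`, `id`, `pos_cM`).
#' @param pedigree Optional `ped_tbl` supplying sire/dam columns.
#' @param ped_path,map_path Output paths.
#' @return `c(ped_path, map_path)`, invisibly.
#' @export
write_plink_text <- function(genotypes, snp_map, ped_path, map_path,
                             pedigree = NULL) {
  stopifnot(nrow(snp_map) == ncol(genotypes))
  ids <- rownames(genotypes)
  sire <- dam <- rep("0", length(ids))
  if (!is.null(pedigree)) {
    i <- match(ids, pedigree$id)
    sire <- ifelse(is.na(pedigree$sire[i]), "0", pedigree$sire[i])
    dam  <- ifelse(is.na(pedigree$dam[i]), "0", pedigree$dam[i])
  }
  allele1 <- ifelse(genotypes >= 1L, "2", "1")
  allele2 <- ifelse(genotypes == 2L, "2", "1")
  inter <- matrix("", nrow(genotypes), 2L * ncol(genotypes))
  inter[, seq(1, ncol(inter), by = 2)] <- allele1
  inter[, seq(2, ncol(inter), by = 2)] <- allele2
  lines <- paste("F0", ids, sire, dam, "0", "-9",
                 apply(inter, 1L, paste, collapse = " "))
  writeLines(lines, ped_path)
  utils::write.table(
    data.frame(snp_map$chromosome, snp_map$id, snp_map$pos_cM, snp_map$index),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(ped_path, map_path))
}

#' Read PLINK text genotypes
#'
#' Reads a `.ped`/`.map` pair with alleles coded 1/2 and no missing calls;
#' genotype codes are counts of allele 2. Positions must be non-decreasing
#' within each chromosome.
#'
#' @param ped_path,map_path Input paths.
#' @return List with `genotypes` (integer matrix, ids as rownames),
#'   `snp_map` (tibble), `ids`.
#' @export
read_plink_text <- function(ped_path, map_path) {
  mp <- utils::read.table(map_path, header = FALSE,
                          col.names = c("chromosome", "id", "pos_cM", "index"))
  for (chr in unique(mp$chromosome)) {
    pos <- mp$pos_cM[mp$chromosome == chr]
    if (is.unsorted(pos)) {
      bad <- which(mp$chromosome == chr)[which(diff(pos) < 0)[1] + 1L]
      stop("map positions not sorted within chromosome ", chr,
           " at line ", bad, " (", mp$id[bad], ")", call. = FALSE)
    }
  }
  snp_map <- tibble::tibble(serial = seq_len(nrow(mp)),
                            chromosome = mp$chromosome, index = mp$index,
                            id = mp$id, pos_cM = mp$pos_cM)
  rows <- strsplit(trimws(readLines(ped_path)), "\\s+")
  m <- nrow(mp)
  ids <- character(length(rows))
  g <- matrix(0L, length(rows), m)
  for (r in seq_along(rows)) {
    f <- rows[[r]]
    if (length(f) != 6 + 2 * m) {
      stop(".ped line ", r, " has ", length(f), " fields, expected ",
           6 + 2 * m, call. = FALSE)
    }
    ids[r] <- f[2]
    al <- f[-(1:6)]
    if (any(al == "0")) {
      stop("missing genotype code at .ped line ", r,
           "; this reader requires complete data", call. = FALSE)
    }
    if (!all(al %in% c("1", "2"))) {
      stop("allele symbol outside {1,2} at .ped line ", r, call. = FALSE)
    }
    ai <- al == "2"
    g[r, ] <- ai[seq(1, 2 * m, by = 2)] + ai[seq(2, 2 * m, by = 2)]
  }
  rownames(g) <- ids
  colnames(g) <- mp$id
  list(genotypes = g, snp_map = snp_map, ids = ids)
}

#' Write all artifacts of a simulated population
#'
#' Emits the pedigree TSV, PLINK `.ped`/`.map`, native genotype TSV,
#' phenotype TSV and the QTN truth table into a directory.
#'
#' @param pop A `sim_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(pop$pedigree, file.path(dir, "pedigree.tsv"))
  write_plink_text(pop$genotypes, pop$map, file.path(dir, "genotypes.ped"),
                   file.path(dir, "genotypes.map"), pop$pedigree)
  write_genotypes_tsv(pop$genotypes, file.path(dir, "genotypes.tsv"))
  write_phenotypes(pop$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_qtn_truth(pop$qtn_truth, file.path(dir, "qtn_truth.tsv"))
  invisible(dir)
}

pipeline_stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  attr(res, "elapsed_s") <- proc.time()[["elapsed"]] - t0
  res
}

#' Run the full association pipeline
#'
#' Chains the analysis stages in their canonical order: restrict the
#' genotypes to parents plus phenotyped progeny, marker QC, REML variance
#' components, the genome-wide single-locus mixed-model scan, the
#' max-statistic permutation threshold (with the Bonferroni threshold for
#' comparison), significant-SNP declaration, and D'/Gabriel LD-block
#' calling among the significant SNPs of each chromosome.
#'
#' Inputs are either a simulation configuration (`sim`) or file paths to a
#' pedigree TSV, genotypes (native TSV or PLINK text) and a phenotype TSV —
#' exactly one of the two modes.
#'
#' @param sim A [sim_config()] for simulation mode.
#' @param pedigree_path,phenotypes_path,genotypes_path,ped_path,map_path
#'   File-mode inputs; `genotypes_path` takes the native TSV, or supply
#'   `ped_path` + `map_path` for PLINK text.
#' @param maf_threshold MAF cutoff (default 0.03).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Seed for the permutation streams (simulation mode also seeds
#'   the generator from `sim$seed`).
#' @param workers Parallel workers for the permutations.
#' @param out_dir Optional directory for result TSVs and the run manifest.
#' @param quiet Suppress per-stage messages? Default `TRUE`.
#' @return A list of class `mmra_pipeline`: `qc`, `vc`, `scan`, `null`,
#'   `thresholds`, `significant`, `blocks`, `ld`, `manifest`.
#' @export
run_pipeline <- function(sim = NULL,
                         pedigree_path = NULL, phenotypes_path = NULL,
                         genotypes_path = NULL, ped_path = NULL,
                         map_path = NULL,
                         maf_threshold = 0.03, alpha = 0.05,
                         n_perm = 10000L, seed = 1L, workers = 1L,
                         out_dir = NULL, quiet = TRUE) {
  sim_mode <- !is.null(sim)
  file_mode <- !is.null(pedigree_path)
  if (sim_mode == file_mode) {
    stop("provide exactly one of: a simulation config, or input file paths",
         call. = FALSE)
  }

  if (sim_mode) {
    pop <- pipeline_stage("simulate", quiet, simulate_population(sim))
    pedigree <- pop$pedigree
    genotypes <- pop$genotypes
    snp_map <- pop$map
    trait <- pop$phenotypes
  } else {
    pedigree <- pipeline_stage("read", quiet, read_pedigree(pedigree_path))
    gio <- pipeline_stage("read_genotypes", quiet, {
      if (!is.null(genotypes_path)) {
        g <- read_genotypes_tsv(genotypes_path)
        list(genotypes = g, snp_map = NULL)
      } else {
        read_plink_text(ped_path, map_path)
      }
    })
    genotypes <- gio$genotypes
    snp_map <- gio$snp_map
    if (is.null(snp_map)) {
      stop("native-TSV mode requires PLINK map input for positions; ",
           "use ped_path/map_path or attach a map", call. = FALSE)
    }
    trait <- read_phenotypes(phenotypes_path)
  }

  keep_ids <- union(pedigree$id[is.na(pedigree$sire) & is.na(pedigree$dam)],
                    trait$id)
  qc <- pipeline_stage("qc", quiet, {
    g_kept <- restrict_individuals(genotypes, keep_ids)
    filter_snps(g_kept, snp_map, maf_threshold)
  })

  A <- pipeline_stage("relationship", quiet, build_A(pedigree))
  vc <- pipeline_stage("reml", quiet,
                       estimate_variance_components(trait, A, pedigree))
  scan <- pipeline_stage("scan", quiet,
                         mmra_scan(qc$genotypes, qc$snp_map, trait, A, vc))
  null <- pipeline_stage("permute", quiet,
                         max_statistic_null(qc$genotypes, qc$snp_map, trait,
                                            A, vc, n_perm = n_perm,
                                            seed = seed, workers = workers))
  perm_wald <- empirical_threshold(null, alpha)
  bonf_p <- bonferroni_threshold(alpha, nrow(scan))
  bonf_wald <- stats::qchisq(bonf_p, 1, lower.tail = FALSE)
  thresholds <- tibble::tibble(
    method = c("permutation", "bonferroni"),
    alpha = rep(alpha, 2),
    wald_threshold = c(perm_wald, bonf_wald),
    p_threshold = c(wald_pvalue(perm_wald), bonf_p)
  )
  sig <- declare_significant(scan, perm_wald)

  ld <- list()
  blocks <- list()
  g_ld <- restrict_individuals(qc$genotypes, keep_ids)
  for (chr in sort(unique(sig$significant$chromosome))) {
    ids_chr <- sig$significant$snp[sig$significant$chromosome == chr]
    if (length(ids_chr) < 2) next
    prs <- pipeline_stage(paste0("ld_chr", chr), quiet,
                          ld_pairs(g_ld, ids_chr))
    map_chr <- qc$snp_map[qc$snp_map$id %in% ids_chr, , drop = FALSE]
    ld[[as.character(chr)]] <- prs
    blocks[[as.character(chr)]] <- gabriel_blocks(prs, map_chr)
  }
  blocks <- if (length(blocks)) dplyr::bind_rows(blocks) else
    gabriel_blocks(tibble::tibble(snp_i = character(0), snp_j = character(0),
                                  ci_low = numeric(0), ci_high = numeric(0)),
                   tibble::tibble(id = character(0), chromosome = 1L,
                                  pos_cM = numeric(0)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mmragwas")),
    seed = seed, n_perm = n_perm, alpha = alpha,
    maf_threshold = maf_threshold,
    mode = if (sim_mode) "simulation" else "files",
    sim_seed = if (sim_mode) sim$seed else NA,
    n_individuals = nrow(pedigree),
    n_phenotyped = nrow(trait),
    n_snps_input = ncol(genotypes),
    n_snps_retained = qc$report$n_retained,
    threshold_rule = "ceil((1-alpha)*n_perm)-th smallest max Wald; strict exceedance"
  )

  out <- structure(list(
    qc = qc, vc = vc, scan = scan, null = null, thresholds = thresholds,
    significant = sig, blocks = blocks, ld = ld, manifest = manifest,
    pedigree = pedigree, trait = trait,
    pop = if (sim_mode) pop else NULL
  ), class = "mmra_pipeline")

  if (!is.null(out_dir)) write_pipeline_results(out, out_dir)
  out
}

#' Write pipeline results to a directory
#'
#' @param result An `mmra_pipeline`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    as.data.frame(x), file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_qc_report(result$qc, file.path(dir, "qc_report.txt"))
  wt(glance(result$vc), "varcomp.tsv")
  wt(result$scan, "scan.tsv")
  wt(tibble::tibble(perm = seq_along(result$null$max_wald),
                    max_wald = result$null$max_wald), "perm_null.tsv")
  wt(result$thresholds, "thresholds.tsv")
  wt(result$significant$significant, "significant_snps.tsv")
  wt(result$significant$by_chromosome, "significant_by_chromosome.tsv")
  if (nrow(result$blocks)) {
    wt(dplyr::select(result$blocks, -"members"), "ld_blocks.tsv")
  } else {
    wt(tibble::tibble(note = "no LD blocks"), "ld_blocks.tsv")
  }
  for (chr in names(result$ld)) {
    wt(result$ld[[chr]], sprintf("ld_pairs_chr%s.tsv", chr))
  }
  mf <- result$manifest
  writeLines(paste(names(mf), vapply(mf, as.character, character(1)),
                   sep = ": "), file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.mmra_pipeline <- function(x, ...) {
  cat("Mixed-model single-locus GWAS pipeline\n")
  cat("  retained SNPs:", x$manifest$n_snps_retained, "of",
      x$manifest$n_snps_input, "\n")
  cat(sprintf("  h^2 = %.3f (sigma_a^2 = %.3f, sigma_e^2 = %.3f)\n",
              x$vc$h2, x$vc$sigma_a2, x$vc$sigma_e2))
  cat("  significant SNPs:", nrow(x$significant$significant),
      "at permutation threshold",
      sprintf("%.2f", x$thresholds$wald_threshold[1]), "\n")
  cat("  LD blocks:", nrow(x$blocks), "\n")
  invisible(x)
}
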