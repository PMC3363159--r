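#' Restrict a genotype matrix to a set of individuals
#'
#' @param genotypes Integer matrix (individuals x SNPs, codes 0/1/2) with
#'   rownames.
#' @param keep_ids Character vector of row ids to keep; order of the matrix
#'   is preserved.
#' @return The row-restricted genotype matrix.
#' @export
restrict_individuals <- function(genotypes, keep_ids) {
  if (is.null(rownames(genotypes))) {
    stop("genotype matrix must have individual ids as rownames", call. = FALSE)
  }
  unknown <- setdiff(keep_ids, rownames(genotypes))
  if (length(unknown)) {
    stop("unknown individual id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (!length(keep_ids)) stop("empty analysis set", call. = FALSE)
  genotypes[rownames(genotypes) %in% keep_ids, , drop = FALSE]
}

#' Minor allele frequency of 0/1/2 genotype codes
#'
#' The frequency of allele 2 is `sum(codes) / (2 n)`; the MAF is the smaller
#' of that frequency and its complement, so it always lies in `[0, 0.5]`.
#'
#' @param genotypes A vector of codes for one SNP, or a matrix
#'   (individuals x SNPs).
#' @return A numeric MAF per SNP.
#' @examples
#' minor_allele_frequency(c(0, 0, 1, 2)) # p2 = 3/8
#' @export
minor_allele_frequency <- function(genotypes) {
  if (is.matrix(genotypes)) {
    if (nrow(genotypes) == 0L) stop("empty genotype matrix", call. = FALSE)
    p2 <- colSums(genotypes) / (2 * nrow(genotypes))
  } else {
    if (!length(genotypes)) stop("empty genotype column", call. = FALSE)
    p2 <- sum(genotypes) / (2 * length(genotypes))
  }
  if (any(p2 < 0 | p2 > 1)) stop("genotype codes must be 0/1/2", call. = FALSE)
  pmin(p2, 1 - p2)
}

#' Marker quality control: drop monomorphic and low-MAF SNPs
#'
#' Computes the minor allele frequency on the supplied (already restricted)
#' individual set and removes SNPs that are monomorphic (MAF = 0) or whose
#' MAF is strictly below `maf_threshold`; a SNP exactly at the threshold is
#' retained. Columns whose allele 2 is in fact the major allele are
#' recoded (`code -> 2 - code`) so that, after filtering, every code counts
#' copies of the minor allele.
#'
#' @param genotypes Genotype matrix (individuals x SNPs, codes 0/1/2).
#' @param snp_map SNP map tibble aligned with the matrix columns.
#' @param maf_threshold MAF cutoff in `[0, 0.5)`; default 0.03.
#' @return A list of class `snp_qc` with elements `genotypes` (recoded,
#'   filtered), `snp_map` (filtered, with a `maf` column), and `report`, a
#'   tibble with `n_input`, `n_monomorphic`, `n_low_maf`, `n_retained`, plus
#'   attribute `retained_index` (original column indices).
#' @examples
#' g <- cbind(a = c(0, 0, 0), b = c(0, 1, 2), c = c(1, 1, 1))
#' rownames(g) <- c("x", "y", "z")
#' map <- tibble::tibble(serial = 1:3, chromosome = 1, index = 1:3,
#'                       id = colnames(g), pos_cM = 1:3 * 0.05)
#' filter_snps(g, map, 0.03)$report
#' @export
filter_snps <- function(genotypes, snp_map, maf_threshold = 0.03) {
  if (maf_threshold < 0 || maf_threshold >= 0.5) {
    stop("maf_threshold must lie in [0, 0.5)", call. = FALSE)
  }
  if (nrow(snp_map) != ncol(genotypes)) {
    stop("snp_map rows must align with genotype columns", call. = FALSE)
  }
  p2 <- colSums(genotypes) / (2 * nrow(genotypes))
  flip <- p2 > 0.5
  if (any(flip)) {
    genotypes[, flip] <- 2L - genotypes[, flip]
    storage.mode(genotypes) <- "integer"
  }
  maf <- pmin(p2, 1 - p2)

  mono <- maf == 0
  low  <- !mono & maf < maf_threshold
  keep <- !mono & !low
  report <- tibble::tibble(
    n_input = length(maf),
    n_monomorphic = sum(mono),
    n_low_maf = sum(low),
    n_retained = sum(keep)
  )
  out_map <- snp_map[keep, , drop = FALSE]
  out_map$maf <- maf[keep]
  out <- list(
    genotypes = genotypes[, keep, drop = FALSE],
    snp_map = out_map,
    report = report
  )
  attr(out, "retained_index") <- which(unname(keep))
  class(out) <- "snp_qc"
  out
}

#' @export
print.snp_qc <- function(x, ...) {
  r <- x$report
  cat("SNP quality control\n")
  cat("  input SNPs:      ", r$n_input, "\n")
  cat("  monomorphic:     ", r$n_monomorphic, "(MAF = 0)\n")
  cat("  low MAF:         ", r$n_low_maf, "\n")
  cat("  retained:        ", r$n_retained, "\n")
  invisible(x)
}

#' Write a QC summary as plain text
#'
#' @param qc A `snp_qc` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  r <- qc$report
  writeLines(c(
    sprintf("n_input\t%d", r$n_input),
    sprintf("n_monomorphic\t%d", r$n_monomorphic),
    sprintf("n_low_maf\t%d", r$n_low_maf),
    sprintf("n_retained\t%d", r$n_retained)
  ), path)
  invisible(path)
}
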