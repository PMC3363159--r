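#' Construct and validate a pedigree
#'
#' A pedigree is a tibble with columns `id`, `sire`, `dam` (character; `NA`
#' means unknown parent), ordered so that every parent appears before its
#' offspring. `as_pedigree()` validates an arbitrary three-column data frame,
#' reordering it topologically when offspring precede their parents, and
#' attaches a `generation` column (0 for founders, 1 + max parental generation
#' otherwise).
#'
#' @param x A data frame with columns `id`, `sire`, `dam`. The literal `"0"`
#'   and empty strings are treated as unknown parents, as is `NA`.
#' @return A tibble of class `ped_tbl` with columns `id`, `sire`, `dam`,
#'   `generation`, topologically ordered.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   id = c("A", "B", "C"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B")
#' ))
#' ped
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("id", "sire", "dam") %in% names(x))) {
    stop("pedigree needs columns id, sire, dam", call. = FALSE)
  }
  id   <- as.character(x$id)
  sire <- as.character(x$sire)
  dam  <- as.character(x$dam)
  sire[sire %in% c("0", "") | is.na(sire)] <- NA_character_
  dam[dam %in% c("0", "") | is.na(dam)] <- NA_character_

  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  parents <- stats::na.omit(unique(c(sire, dam)))
  missing_par <- setdiff(parents, id)
  if (length(missing_par)) {
    stop("parent id(s) never defined as individuals: ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id)) {
    stop("individual listed as its own parent (pedigree cycle)", call. = FALSE)
  }

  # Kahn topological sort; detects any remaining cycles.
  n <- length(id)
  pos <- stats::setNames(seq_len(n), id)
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])
  gen <- rep(NA_integer_, n)
  order_out <- integer(0)
  ready <- which(si == 0L & di == 0L)
  gen[ready] <- 0L
  placed <- rep(FALSE, n)
  queue <- ready
  while (length(queue)) {
    order_out <- c(order_out, queue)
    placed[queue] <- TRUE
    par_gen <- gen
    avail <- which(!placed &
                   (si == 0L | placed[pmax(si, 1L)]) &
                   (di == 0L | placed[pmax(di, 1L)]))
    if (!length(avail)) break
    for (i in avail) {
      g <- 0L
      if (si[i] > 0L) g <- max(g, par_gen[si[i]] + 1L)
      if (di[i] > 0L) g <- max(g, par_gen[di[i]] + 1L)
      gen[i] <- g
    }
    queue <- avail
  }
  if (length(order_out) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(id[!placed], collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(
    id = id[order_out], sire = sire[order_out], dam = dam[order_out],
    generation = gen[order_out]
  )
  class(out) <- c("ped_tbl", class(out))
  out
}

#' Read a pedigree file
#'
#' Reads a whitespace-separated file with three columns (individual, sire,
#' dam; `0` or `NA` for unknown parents), validates it and returns it in
#' parents-first order.
#'
#' @param path Path to the pedigree file. A header line starting with `id` is
#'   allowed and skipped.
#' @return A `ped_tbl` tibble (see [as_pedigree()]).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "sire", "dam"))
  if (nrow(raw) && tolower(raw$id[1]) == "id") raw <- raw[-1, , drop = FALSE]
  as_pedigree(raw)
}

#' Write a pedigree to a TSV file
#'
#' @param pedigree A `ped_tbl`.
#' @param path Output path; columns id, sire, dam with `0` for unknown.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- data.frame(
    id = pedigree$id,
    sire = ifelse(is.na(pedigree$sire), "0", pedigree$sire),
    dam = ifelse(is.na(pedigree$dam), "0", pedigree$dam)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Additive genetic relationship matrix
#'
#' Builds the dense numerator relationship matrix A by the tabular
#' (recursive) method: for individual i with parents s and d (in
#' parents-first order), `a_ii = 1 + a_sd / 2` and
#' `a_ij = (a_js + a_jd) / 2` for every earlier j; an unknown parent
#' contributes zero. Founders are mutually unrelated and non-inbred, so
#' their diagonal is exactly 1.
#'
#' @param pedigree A `ped_tbl` (or a data frame coercible via
#'   [as_pedigree()]).
#' @return A symmetric numeric matrix with dimnames equal to the pedigree
#'   ids, in pedigree order. Diagonal entries are `1 + F`, where F is the
#'   inbreeding coefficient.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   id = c("A", "B", "C"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B")
#' ))
#' build_A(ped) # trio: off-diagonals 0.5
#' @export
build_A <- function(pedigree) {
  pedigree <- if (inherits(pedigree, "ped_tbl")) pedigree else as_pedigree(pedigree)
  n <- nrow(pedigree)
  pos <- stats::setNames(seq_len(n), pedigree$id)
  si <- ifelse(is.na(pedigree$sire), 0L, pos[pedigree$sire])
  di <- ifelse(is.na(pedigree$dam), 0L, pos[pedigree$dam])
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (s > 0L) A[j, s] else 0
      row_d <- if (d > 0L) A[j, d] else 0
      aij <- 0.5 * (row_s + row_d)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' `F_i` is half the additive relationship between the parents of i; zero for
#' founders and individuals with any unknown parent.
#'
#' @inheritParams build_A
#' @return A tibble with columns `id` and `F`.
#' @export
inbreeding <- function(pedigree) {
  pedigree <- if (inherits(pedigree, "ped_tbl")) pedigree else as_pedigree(pedigree)
  A <- build_A(pedigree)
  tibble::tibble(id = pedigree$id, F = unname(diag(A)) - 1)
}
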