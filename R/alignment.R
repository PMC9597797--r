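#' Alignment as a character matrix
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @return Character matrix, rows = sequences (rownames = ids), columns = sites.
#' @export
aln_matrix <- function(aln) {
  stopifnot(is.character(aln), length(aln) >= 1L)
  L <- unique(nchar(aln))
  if (length(L) != 1L)
    stop("sequences have unequal lengths: ", paste(L, collapse = ", "))
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  m
}

aln_collapse <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

is_missing_char <- function(x) x %in% c("N", "-", "?")

#' Trim alignment columns protruding beyond the reference sequences
#'
#' Columns before the first and after the last position covered (non-gap) by
#' every reference sequence are removed, so the analysis span is the region all
#' references jointly cover.
#'
#' @param aln Named character vector of aligned sequences.
#' @param reference_ids Ids of the reference sequences defining the span.
#' @return Trimmed alignment with attribute `kept_columns` (1-based, inclusive).
#' @export
trim_protruding_ends <- function(aln, reference_ids) {
  stopifnot(length(reference_ids) >= 1L)
  missing_ref <- setdiff(reference_ids, names(aln))
  if (length(missing_ref))
    stop("reference id(s) absent from alignment: ",
         paste(missing_ref, collapse = ", "))
  m <- aln_matrix(aln)
  covered <- m[reference_ids, , drop = FALSE] != "-"
  first <- max(apply(covered, 1L, function(z) {
    w <- which(z); if (length(w)) w[1L] else Inf
  }))
  last <- min(apply(covered, 1L, function(z) {
    w <- which(z); if (length(w)) w[length(w)] else -Inf
  }))
  if (!is.finite(first) || !is.finite(last) || first > last)
    stop("reference sequences share no covered span")
  out <- aln_collapse(m[, first:last, drop = FALSE])
  attr(out, "kept_columns") <- c(first, last)
  out
}

#' Conserved-block column mask (Gblocks-style)
#'
#' Re-implementation in the spirit of the classic conserved-block selector for
#' phylogenetics: a column is conserved when its majority residue reaches
#' `min_conserved` of the sequences (and, with `allow_gaps = FALSE`, carries no
#' gap), and highly conserved when it reaches `min_flank`. Retained columns
#' form blocks of at least `min_block_len` columns whose two termini are highly
#' conserved and which contain no run of more than `max_nonconserved_run`
#' non-conserved columns. It is faithful in spirit, not byte-compatible with
#' the original program.
#'
#' @param aln Named character vector of aligned sequences (n >= 2).
#' @param min_conserved Minimum majority-residue count for a conserved column;
#'   default `floor(n/2) + 1`.
#' @param min_flank Minimum majority-residue count for a block terminus;
#'   default `ceiling(0.85 * n)`.
#' @param max_nonconserved_run Longest tolerated run of non-conserved columns
#'   inside a block.
#' @param min_block_len Minimum block length.
#' @param allow_gaps If `FALSE` (default), any column containing a gap is
#'   non-conserved and is never retained, even inside an otherwise kept block.
#' @return Logical vector over columns: `TRUE` = retained.
#' @export
conserved_block_mask <- function(aln, min_conserved = NULL, min_flank = NULL,
                                 max_nonconserved_run = 8L, min_block_len = 10L,
                                 allow_gaps = FALSE) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  if (is.null(min_conserved)) min_conserved <- floor(n / 2) + 1L
  if (is.null(min_flank)) min_flank <- ceiling(0.85 * n)

  gapped <- apply(m, 2L, function(col) any(col == "-"))
  status <- apply(m, 2L, function(col) {
    res <- col[col %in% c("A", "C", "G", "T")]
    maj <- if (length(res)) max(table(res)) else 0L
    if (maj >= min_flank) 2L else if (maj >= min_conserved) 1L else 0L
  })
  if (!allow_gaps) status[gapped] <- 0L

  mask <- logical(length(status))
  # split candidate segments at over-long non-conserved runs
  runs <- rle(status == 0L)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  breakers <- runs$values & runs$lengths > max_nonconserved_run
  cuts <- which(breakers)
  # segments are the stretches between (and around) the breaking runs
  seg_start <- c(1L, ends[cuts] + 1L)
  seg_end <- c(starts[cuts] - 1L, length(status))
  for (k in seq_along(seg_start)) {
    i <- seg_start[k]; j <- seg_end[k]
    if (i > j) next
    while (i <= j && status[i] != 2L) i <- i + 1L
    while (j >= i && status[j] != 2L) j <- j - 1L
    if (j - i + 1L >= min_block_len) mask[i:j] <- TRUE
  }
  if (!allow_gaps) mask[gapped] <- FALSE
  mask
}

#' Drop alignment columns with too much missing data
#'
#' Columns whose fraction of missing symbols (`N`, `-`, `?`) exceeds
#' `max_missing_frac` are removed; the standard pre-filter before
#' population-differentiation statistics.
#'
#' @param aln Named character vector of aligned sequences.
#' @param max_missing_frac Maximum tolerated missing fraction per column.
#' @return Filtered alignment with attribute `kept_columns` (1-based indices).
#' @export
drop_high_missing_loci <- function(aln, max_missing_frac = 0.05) {
  m <- aln_matrix(aln)
  frac <- colMeans(matrix(is_missing_char(m), nrow = nrow(m)))
  keep <- which(frac <= max_missing_frac)
  out <- aln_collapse(m[, keep, drop = FALSE])
  attr(out, "kept_columns") <- keep
  out
}

#' Apply a logical column mask to an alignment
#' @param aln Named character vector of aligned sequences.
#' @param mask Logical vector, one element per column.
#' @return Alignment restricted to the masked-in columns.
#' @export
apply_column_mask <- function(aln, mask) {
  m <- aln_matrix(aln)
  stopifnot(is.logical(mask), length(mask) == ncol(m))
  aln_collapse(m[, mask, drop = FALSE])
}
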