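#' Read a FASTA file of D-loop haplotype sequences
#'
#' Sequences are upper-cased on input; record ids are taken from the first
#' whitespace-delimited token of each header line and must be unique.
#' Only the nucleotide alphabet `A C G T`, the ambiguity code `N` and the
#' alignment gap `-` are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record, names = ids.
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(stats::setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("malformed FASTA at line ", nonblank[1L], ": expected a '>' header")
  body <- setdiff(nonblank, grep("^>", lines))
  bad <- body[grepl("[^ACGTNacgtn-]", gsub("[[:space:]]", "", lines[body]))]
  if (length(bad))
    stop("illegal sequence character at line ", bad[1L], ": ", sQuote(lines[bad[1L]]))
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1L), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("empty id in FASTA header")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read a breed metadata table
#'
#' Tab-separated with header `id  breed  region  tail`. Breed codes follow the
#' 4-letter upper-case convention; other codes are accepted with a warning.
#' Tail phenotypes are restricted to `thin`, `fat`, `fat_rumped`, `fat_base`
#' (missing allowed for wild accessions).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `id`, `breed`, `region`, `tail`.
#' @export
read_breed_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_breed_table(tab)
}

#' @rdname read_breed_table
#' @param tab A data.frame to validate as a breed table.
#' @export
validate_breed_table <- function(tab) {
  need <- c("id", "breed", "region", "tail")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("breed table lacks column(s): ", paste(miss, collapse = ", "))
  tab <- tab[need]
  if (anyDuplicated(tab$id)) stop("duplicate id in breed table: ",
                                  tab$id[duplicated(tab$id)][1L])
  odd <- unique(tab$breed[!grepl("^[A-Z0-9]{4}$", tab$breed)])
  if (length(odd))
    warning("breed code(s) not in the 4-letter upper-case convention: ",
            paste(odd, collapse = ", "))
  tails <- c("thin", "fat", "fat_rumped", "fat_base")
  badt <- stats::na.omit(setdiff(unique(tab$tail), c(tails, "", NA)))
  if (length(badt)) stop("unknown tail phenotype(s): ", paste(badt, collapse = ", "))
  tab
}

#' Write a breed metadata table
#' @param tab Breed table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breed_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

breed_of <- function(ids, breed_table) {
  b <- breed_table$breed[match(ids, breed_table$id)]
  if (anyNA(b))
    stop("id(s) missing from the breed table: ",
         paste(utils::head(ids[is.na(b)], 5L), collapse = ", "))
  b
}

#' Remove byte-identical sequences within each breed
#'
#' Identical haplotypes sampled from the same breed are collapsed to a single
#' representative (the lexicographically smallest id) to discard possibly
#' related animals. Identical sequences occurring in different breeds are all
#' kept: the rule is strictly within-breed.
#'
#' @param seqs Named character vector of (aligned or trimmed) sequences.
#' @param breed_table Breed table covering every sequence id.
#' @return A list with `kept` (subset of `seqs`, original order) and `report`
#'   (data.frame of `removed_id`, `representative`, `breed`).
#' @export
dedup_identical_within_breed <- function(seqs, breed_table) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  breeds <- breed_of(names(seqs), breed_table)
  key <- paste(breeds, seqs, sep = "\r")
  rep_id <- vapply(split(names(seqs), key), function(ids) min(ids), character(1L))
  keep <- names(seqs) %in% rep_id
  removed <- names(seqs)[!keep]
  report <- data.frame(
    removed_id = removed,
    representative = unname(rep_id[key[!keep]]),
    breed = breeds[!keep],
    stringsAsFactors = FALSE
  )
  list(kept = seqs[keep], report = report)
}

#' Count mismatches between two equal-length sequences
#'
#' Positions where either sequence carries a gap (`-`), an `N` or a `?` are
#' skipped (pairwise deletion).
#'
#' @param s1,s2 Sequence strings of equal length.
#' @return Integer mismatch count over the shared resolved positions.
#' @export
count_mismatches <- function(s1, s2) {
  if (nchar(s1) != nchar(s2))
    stop("sequences are not aligned to the same length (",
         nchar(s1), " vs ", nchar(s2), ")")
  a <- strsplit(s1, "")[[1L]]
  b <- strsplit(s2, "")[[1L]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[ok] != b[ok])
}

#' Retain breeds with enough near-identical matches to a seed sequence
#'
#' Emulates the database-expansion rule: candidate sequences within
#' `max_mismatch` mutations of the seed are counted per breed, and breeds with
#' at least `min_breed_occurrence` such candidates are retained.
#'
#' @param seed Seed sequence (single string), aligned to the candidates.
#' @param candidates Named character vector of candidate sequences.
#' @param candidate_breeds Character vector of breed codes, parallel to
#'   `candidates` (or a breed table; ids are then matched by name).
#' @param max_mismatch Maximum mutations separating a hit from the seed.
#' @param min_breed_occurrence Minimum number of hits for a breed to be kept.
#' @return Sorted character vector of retained breed codes.
#' @export
filter_candidate_pool <- function(seed, candidates, candidate_breeds,
                                  max_mismatch = 2L, min_breed_occurrence = 2L) {
  stopifnot(length(seed) == 1L)
  if (is.data.frame(candidate_breeds))
    candidate_breeds <- breed_of(names(candidates), candidate_breeds)
  stopifnot(length(candidate_breeds) == length(candidates))
  mm <- vapply(candidates, count_mismatches, integer(1L), s1 = seed)
  hits <- candidate_breeds[mm <= max_mismatch]
  tallies <- table(hits)
  sort(as.character(names(tallies)[tallies >= min_breed_occurrence]))
}
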