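#' Pairwise difference matrix between aligned sequences
#'
#' Distance = number of differing resolved positions, with pairwise deletion
#' of gaps, `N` and `?` (the standard treatment for DNA haplotypes in
#' molecular-variance analyses).
#'
#' @param aln Named character vector of aligned sequences.
#' @return Symmetric integer matrix of difference counts.
#' @export
pairwise_diff_matrix <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  resolved <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  D <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- resolved[i, ] & resolved[j, ]
    D[i, j] <- D[j, i] <- sum(m[i, ok] != m[j, ok])
  }
  D
}

phi_st_from_distances <- function(D, pop) {
  pop <- as.character(pop)
  sizes <- table(pop)
  P <- length(sizes)
  N <- length(pop)
  D2 <- D^2
  ssd_total <- sum(D2) / (2 * N)
  ssd_within <- 0
  for (p in names(sizes)) {
    idx <- which(pop == p)
    ssd_within <- ssd_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - P)
  n_bar <- (N - sum(sizes^2) / N) / (P - 1)
  sigma_a <- (ssd_among / (P - 1) - sigma_w) / n_bar
  denom <- sigma_a + sigma_w
  if (denom <= 0) {
    warning("zero total molecular variance: Phi-ST defined as 0")
    return(0)
  }
  sigma_a / denom
}

#' Pairwise Phi-ST between two populations of haplotype sequences
#'
#' Distance-based analysis of molecular variance on the matrix of pairwise
#' difference counts: with N sequences in P = 2 populations,
#' `SSD_total = sum(d^2) / 2N` over ordered pairs, `SSD_within` the analogous
#' per-population sum, `sigma2_w = SSD_within / (N - P)`,
#' `sigma2_a = (SSD_among / (P - 1) - sigma2_w) / n_bar` with `n_bar` the
#' size-corrected average sample size, and
#' `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)`. Negative estimates are
#' reported as computed unless `clamp_negative = TRUE`.
#'
#' @param pop1_seqs,pop2_seqs Character vectors (>= 2 sequences each) of
#'   equal-length aligned sequences.
#' @param clamp_negative If `TRUE`, negative estimates are clamped to 0.
#' @return Phi-ST estimate in `[-1, 1]`.
#' @export
pairwise_phi_st <- function(pop1_seqs, pop2_seqs, clamp_negative = FALSE) {
  stopifnot(length(pop1_seqs) >= 2L, length(pop2_seqs) >= 2L)
  seqs <- c(pop1_seqs, pop2_seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (anyDuplicated(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  pop <- rep(c("p1", "p2"), c(length(pop1_seqs), length(pop2_seqs)))
  D <- pairwise_diff_matrix(seqs)
  phi <- phi_st_from_distances(D, pop)
  if (clamp_negative) phi <- max(phi, 0)
  phi
}

#' Permutation p-value for a pairwise Phi-ST
#'
#' Individuals are permuted between the two populations; the p-value is the
#' fraction of permuted statistics at least as large as the observed one,
#' with the (b + 1)/(n + 1) correction.
#'
#' @param pop1_seqs,pop2_seqs Aligned sequences per population.
#' @param n_perm Number of permutations.
#' @param seed Integer seed fixing the permutation stream.
#' @return List with `phi_st` (observed) and `p_value`.
#' @export
phi_st_permutation_p <- function(pop1_seqs, pop2_seqs, n_perm = 1000L, seed = 1L) {
  n1 <- length(pop1_seqs)
  seqs <- c(pop1_seqs, pop2_seqs)
  names(seqs) <- paste0("s", seq_along(seqs))
  pop <- rep(c("p1", "p2"), c(n1, length(pop2_seqs)))
  D <- pairwise_diff_matrix(seqs)
  obs <- suppressWarnings(phi_st_from_distances(D, pop))
  set.seed(seed)
  b <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample(pop)
    val <- suppressWarnings(phi_st_from_distances(D, perm))
    if (val >= obs - 1e-12) b <- b + 1L
  }
  list(phi_st = obs, p_value = (b + 1) / (n_perm + 1))
}

#' Population and locus filters preceding Phi-ST
#'
#' Removes populations with fewer than `min_individuals` sequences, then drops
#' alignment columns with more than `max_missing_frac` missing data.
#'
#' @param aln Named character vector of aligned sequences.
#' @param breed_table Breed table resolving every id.
#' @param min_individuals Minimum population size to retain (default 3).
#' @param max_missing_frac Maximum missing fraction per column (default 0.05).
#' @return List with filtered `aln`, `breed_table`, and `dropped_populations`.
#' @export
apply_population_filters <- function(aln, breed_table, min_individuals = 3L,
                                     max_missing_frac = 0.05) {
  breeds <- breed_of(names(aln), breed_table)
  sizes <- table(breeds)
  dropped <- names(sizes)[sizes < min_individuals]
  keep <- !(breeds %in% dropped)
  aln <- aln[keep]
  aln <- drop_high_missing_loci(aln, max_missing_frac)
  list(aln = aln,
       breed_table = breed_table[breed_table$id %in% names(aln), , drop = FALSE],
       dropped_populations = dropped)
}

#' Pairwise Phi-ST matrix over all populations
#'
#' @param aln Named character vector of aligned sequences.
#' @param breed_table Breed table resolving every id.
#' @param clamp_negative Clamp negative pairwise estimates to 0.
#' @return Object of class `phist_matrix`: list with `populations`, `values`
#'   (symmetric matrix, zero diagonal) and `n_per_pop`.
#' @export
phi_st_matrix <- function(aln, breed_table, clamp_negative = FALSE) {
  pop <- breed_of(names(aln), breed_table)
  pops <- sort(unique(pop))
  sizes <- table(pop)[pops]
  if (any(sizes < 2L))
    stop("population(s) with fewer than 2 sequences: ",
         paste(pops[sizes < 2L], collapse = ", "))
  D <- pairwise_diff_matrix(aln)
  V <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(length(pops) - 1L)) for (j in (i + 1L):length(pops)) {
    idx <- pop %in% pops[c(i, j)]
    phi <- suppressWarnings(
      phi_st_from_distances(D[idx, idx, drop = FALSE], pop[idx]))
    if (clamp_negative) phi <- max(phi, 0)
    V[i, j] <- V[j, i] <- phi
  }
  structure(list(populations = pops, values = V,
                 n_per_pop = as.integer(sizes)),
            class = "phist_matrix")
}

#' @export
print.phist_matrix <- function(x, ...) {
  cat("Pairwise Phi-ST over", length(x$populations), "populations\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Write/read a Phi-ST matrix as TSV
#' @param x A `phist_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phist_matrix <- function(x, path) {
  utils::write.table(x$values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_phist_matrix
#' @export
read_phist_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  structure(list(populations = rownames(m), values = m,
                 n_per_pop = NA_integer_),
            class = "phist_matrix")
}
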