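# Independent brute-force oracles used to check the package's implementations.
# Each is written as a direct transcription of the defining rule, on a
# different code path from the functions it checks.

# --- tree pattern enumeration ------------------------------------------------

tree_parents <- function(tree) {
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

# type-1: enumerate tip pairs sharing a parent (generalized to every pair of
# tip children under a common node)
oracle_type1 <- function(tree) {
  ntip <- ape::Ntip(tree)
  parent <- tree_parents(tree)
  out <- list()
  for (i in seq_len(ntip - 1L)) for (j in (i + 1L):ntip) {
    if (parent[i] == parent[j]) {
      out[[length(out) + 1L]] <- sort(tree$tip.label[c(i, j)])
    }
  }
  if (!length(out)) return(matrix(character(0), ncol = 2L))
  do.call(rbind, out)
}

# type-2: enumerate from each tip — it forms a triple iff its parent is
# binary and its sibling is a two-tip cherry
oracle_type2 <- function(tree) {
  ntip <- ape::Ntip(tree)
  parent <- tree_parents(tree)
  out <- list()
  for (i in seq_len(ntip)) {
    p <- parent[i]
    sibs <- setdiff(which(parent == p), i)
    if (length(sibs) != 1L || sibs <= ntip) next
    cherry_tips <- which(parent == sibs)
    if (length(cherry_tips) == 2L && all(cherry_tips <= ntip)) {
      out[[length(out) + 1L]] <-
        c(tree$tip.label[i], sort(tree$tip.label[cherry_tips]))
    }
  }
  if (!length(out)) return(matrix(character(0), ncol = 3L))
  do.call(rbind, out)
}

# accumulate a link list into a symmetric breed matrix, independently of
# connection_matrix()
oracle_breed_counts <- function(links, tipbreed) {
  breeds <- sort(unique(unname(tipbreed)))
  M <- matrix(0L, length(breeds), length(breeds), dimnames = list(breeds, breeds))
  for (r in seq_len(nrow(links))) {
    b <- sort(tipbreed[unlist(links[r, ])])
    if (b[1L] == b[2L]) M[b[1L], b[1L]] <- M[b[1L], b[1L]] + 1L
    else {
      M[b[1L], b[2L]] <- M[b[1L], b[2L]] + 1L
      M[b[2L], b[1L]] <- M[b[2L], b[1L]] + 1L
    }
  }
  M
}

# --- AMOVA -------------------------------------------------------------------

# Phi-ST by explicit sums over all ordered sequence pairs
oracle_phi_st <- function(pops) {
  seqs <- unlist(pops, use.names = FALSE)
  labels <- rep(seq_along(pops), lengths(pops))
  N <- length(seqs)
  P <- length(pops)
  d <- function(x, y) {
    a <- strsplit(x, "")[[1L]]; b <- strsplit(y, "")[[1L]]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    sum(a[ok] != b[ok])
  }
  ssd_total <- 0
  for (i in seq_len(N)) for (j in seq_len(N))
    ssd_total <- ssd_total + d(seqs[i], seqs[j])^2
  ssd_total <- ssd_total / (2 * N)
  ssd_within <- 0
  for (p in seq_len(P)) {
    idx <- which(labels == p)
    acc <- 0
    for (i in idx) for (j in idx) acc <- acc + d(seqs[i], seqs[j])^2
    ssd_within <- ssd_within + acc / (2 * length(idx))
  }
  sizes <- lengths(pops)
  sigma_w <- ssd_within / (N - P)
  n_bar <- (N - sum(sizes^2) / N) / (P - 1)
  sigma_a <- ((ssd_total - ssd_within) / (P - 1) - sigma_w) / n_bar
  if (sigma_a + sigma_w <= 0) return(0)
  sigma_a / (sigma_a + sigma_w)
}

# --- UPGMA -------------------------------------------------------------------

# step-by-step average-linkage agglomeration; returns the cophenetic matrix
oracle_upgma_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  dmat <- D
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(active) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      a <- active[ii]; b <- active[jj]
      if (dmat[a, b] < bestd - 1e-12) { bestd <- dmat[a, b]; best <- c(a, b) }
    }
    a <- best[1L]; b <- best[2L]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- coph[j, i] <- bestd
    }
    merged <- c(clusters[[a]], clusters[[b]])
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (c0 in setdiff(active, c(a, b))) {
      dmat[a, c0] <- dmat[c0, a] <- (na * dmat[a, c0] + nb * dmat[b, c0]) / (na + nb)
    }
    clusters[[a]] <- merged
    active <- setdiff(active, b)
  }
  coph
}

# --- conserved-block scan ----------------------------------------------------

# column status, as defined by the masking rule
oracle_block_status <- function(m, min_conserved, min_flank, allow_gaps) {
  vapply(seq_len(ncol(m)), function(c0) {
    col <- m[, c0]
    if (!allow_gaps && any(col == "-")) return(0L)
    res <- col[col %in% c("A", "C", "G", "T")]
    if (!length(res)) return(0L)
    maj <- max(table(res))
    if (maj >= min_flank) 2L else if (maj >= min_conserved) 1L else 0L
  }, integer(1L))
}

# union of all windows satisfying the block rules verbatim
oracle_block_mask <- function(aln, min_conserved = NULL, min_flank = NULL,
                              max_run = 8L, min_len = 10L, allow_gaps = FALSE) {
  m <- do.call(rbind, strsplit(aln, ""))
  n <- nrow(m)
  if (is.null(min_conserved)) min_conserved <- floor(n / 2) + 1L
  if (is.null(min_flank)) min_flank <- ceiling(0.85 * n)
  status <- oracle_block_status(m, min_conserved, min_flank, allow_gaps)
  L <- length(status)
  mask <- logical(L)
  for (i in seq_len(L)) for (j in i:L) {
    if (j - i + 1L < min_len) next
    if (status[i] != 2L || status[j] != 2L) next
    runs <- rle(status[i:j] == 0L)
    if (any(runs$values & runs$lengths > max_run)) next
    mask[i:j] <- TRUE
  }
  if (!allow_gaps) {
    gapped <- apply(m, 2L, function(col) any(col == "-"))
    mask[gapped] <- FALSE
  }
  mask
}

# --- fixtures ----------------------------------------------------------------

random_seqs <- function(n, len, ids = sprintf("s%02d", seq_len(n)),
                        alphabet = c("A", "C", "G", "T")) {
  stats::setNames(vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1L)),
    ids)
}

make_breed_table <- function(ids, breeds, region = "Egypt", tail = "thin") {
  data.frame(id = ids, breed = breeds, region = region, tail = tail,
             stringsAsFactors = FALSE)
}

# random breed assignment for a tree's tips
random_breeds <- function(tree, n_breeds = 4L) {
  br <- sprintf("BR%02d", seq_len(n_breeds))
  make_breed_table(tree$tip.label,
                   sample(br, length(tree$tip.label), replace = TRUE))
}

sorted_rows <- function(m) {
  if (!nrow(m)) return(m)
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}
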