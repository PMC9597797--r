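#' Type-1 kinship pairs: strictly sister sequences
#'
#' A type-1 connection links the two tips of a cherry (an internal node whose
#' children are exactly two tips). For a polytomy with m >= 2 tip children the
#' counting generalizes to all `choose(m, 2)` tip pairs under that node; the
#' generalization is announced with a message because trees exported from
#' likelihood programs are binary.
#'
#' @param tree Rooted `phylo` object.
#' @return Two-column character matrix of tip-id pairs (one row per link).
#' @export
find_type1_pairs <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  pairs <- list()
  polytomy_seen <- FALSE
  for (node in names(kids)) {
    ch <- kids[[node]]
    tipch <- ch[ch <= ntip]
    if (length(ch) > 2L && length(tipch) >= 2L) polytomy_seen <- TRUE
    if (length(tipch) >= 2L) {
      cmb <- utils::combn(sort(tree$tip.label[tipch]), 2L)
      pairs[[node]] <- t(cmb)
    }
  }
  if (polytomy_seen)
    message("polytomy encountered: counting all tip pairs under multifurcating nodes")
  out <- do.call(rbind, pairs)
  if (is.null(out)) out <- matrix(character(0), ncol = 2L)
  dimnames(out) <- list(NULL, c("tip1", "tip2"))
  out
}

#' Type-2 kinship triples: a tip sister to an embedded cherry
#'
#' For every internal node with exactly two children, one a tip `t` and the
#' other a cherry `{x, y}`, the triple `(t, x, y)` is emitted; it contributes
#' the two connections t–x and t–y. The internal x–y link is a type-1
#' connection and is not re-counted here.
#'
#' @param tree Rooted `phylo` object.
#' @return Three-column character matrix (`tip`, `cherry1`, `cherry2`).
#' @export
find_type2_triples <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  is_cherry <- function(node) {
    ch <- kids[[as.character(node)]]
    !is.null(ch) && length(ch) == 2L && all(ch <= ntip)
  }
  triples <- list()
  for (node in names(kids)) {
    ch <- kids[[node]]
    if (length(ch) != 2L) next
    tipch <- ch[ch <= ntip]
    intch <- ch[ch > ntip]
    if (length(tipch) == 1L && length(intch) == 1L && is_cherry(intch)) {
      xy <- sort(tree$tip.label[kids[[as.character(intch)]]])
      triples[[node]] <- c(tree$tip.label[tipch], xy)
    }
  }
  out <- do.call(rbind, triples)
  if (is.null(out)) out <- matrix(character(0), ncol = 3L)
  dimnames(out) <- list(NULL, c("tip", "cherry1", "cherry2"))
  out
}

#' Breed-by-breed connection matrix from tree topology
#'
#' Accumulates type-1 pairs or type-2 triples into a symmetric breed-indexed
#' count matrix. Between-breed links increment both mirrored off-diagonal
#' cells; within-breed links increment the diagonal.
#'
#' @param tree Rooted `phylo` object.
#' @param breed_table Breed table resolving every tip id.
#' @param kinship_type 1 (strict sisters) or 2 (tip sister to a cherry).
#' @return Object of class `connection_matrix`: list with `breeds`, `counts`
#'   (symmetric integer matrix), `kinship_type` and `n_links`.
#' @export
connection_matrix <- function(tree, breed_table, kinship_type = 1L) {
  kinship_type <- as.integer(kinship_type)
  stopifnot(kinship_type %in% c(1L, 2L))
  tipbreed <- stats::setNames(breed_of(tree$tip.label, breed_table), tree$tip.label)
  breeds <- sort(unique(unname(tipbreed)))
  counts <- matrix(0L, length(breeds), length(breeds),
                   dimnames = list(breeds, breeds))
  links <- if (kinship_type == 1L) {
    find_type1_pairs(tree)
  } else {
    tr3 <- find_type2_triples(tree)
    rbind(tr3[, c("tip", "cherry1"), drop = FALSE],
          tr3[, c("tip", "cherry2"), drop = FALSE])
  }
  for (r in seq_len(nrow(links))) {
    b1 <- tipbreed[[links[r, 1L]]]
    b2 <- tipbreed[[links[r, 2L]]]
    if (b1 == b2) {
      counts[b1, b1] <- counts[b1, b1] + 1L
    } else {
      counts[b1, b2] <- counts[b1, b2] + 1L
      counts[b2, b1] <- counts[b2, b1] + 1L
    }
  }
  structure(list(breeds = breeds, counts = counts,
                 kinship_type = kinship_type, n_links = nrow(links)),
            class = "connection_matrix")
}

#' @export
print.connection_matrix <- function(x, ...) {
  cat("Breed connection matrix (kinship type ", x$kinship_type, ")\n",
      length(x$breeds), " breeds, ", x$n_links, " links\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Write/read a connection matrix as TSV
#' @param x A `connection_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connection_matrix <- function(x, path) {
  utils::write.table(x$counts, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_connection_matrix
#' @param kinship_type Kinship type to record on the read-back object.
#' @export
read_connection_matrix <- function(path, kinship_type = NA_integer_) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  storage.mode(m) <- "integer"
  structure(list(breeds = rownames(m), counts = m,
                 kinship_type = kinship_type,
                 n_links = NA_integer_),
            class = "connection_matrix")
}

#' Grouped percentage profile of one breed's connections
#'
#' Partner counts are merged by a region/group map, converted to percentages
#' of the focal breed's total over all partners, ranked by count, and retained
#' greedily until the cumulative percentage reaches `100 * retention_fraction`
#' (the presentation used for per-breed connection histograms).
#'
#' @param x A `connection_matrix`.
#' @param focal Focal breed code.
#' @param grouping Optional named character vector `breed -> group`; breeds
#'   absent from the map keep their own code.
#' @param retention_fraction Fraction of total links to cover, in (0, 1].
#' @param include_self If `TRUE`, within-breed (diagonal) links count as a
#'   partner; by default they are excluded.
#' @return Object of class `breed_profile`: list with `focal`, `table`
#'   (partner, count, percent, retained flag), `total_links` and
#'   `retained_fraction` actually covered.
#' @export
breed_profile <- function(x, focal, grouping = NULL, retention_fraction = 1,
                          include_self = FALSE) {
  stopifnot(inherits(x, "connection_matrix"))
  if (!focal %in% x$breeds) stop("focal breed not in matrix: ", focal)
  stopifnot(retention_fraction > 0, retention_fraction <= 1)
  counts <- x$counts[focal, ]
  if (!include_self) counts <- counts[names(counts) != focal]
  partner <- names(counts)
  if (!is.null(grouping)) {
    mapped <- grouping[partner]
    partner <- ifelse(is.na(mapped), partner, mapped)
  }
  agg <- tapply(counts, partner, sum)
  agg <- agg[agg > 0]  # partners without links do not appear in the profile
  agg <- agg[order(-agg, names(agg))]
  total <- sum(agg)
  if (total == 0) {
    warning("breed ", focal, " has no links")
    tab <- data.frame(partner = character(0), count = integer(0),
                      percent = numeric(0), retained = logical(0))
    return(structure(list(focal = focal, table = tab, total_links = 0L,
                          retained_fraction = 0), class = "breed_profile"))
  }
  percent <- 100 * agg / total
  cum <- cumsum(percent)
  n_keep <- which(cum >= 100 * retention_fraction - 1e-9)[1L]
  retained <- seq_along(agg) <= n_keep
  tab <- data.frame(partner = names(agg), count = as.integer(agg),
                    percent = as.numeric(percent), retained = retained,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(focal = focal, table = tab, total_links = as.integer(total),
                 retained_fraction = unname(cum[n_keep]) / 100),
            class = "breed_profile")
}

#' @export
print.breed_profile <- function(x, ...) {
  cat("Connection profile of ", x$focal, " (", x$total_links, " links, ",
      round(100 * x$retained_fraction, 1), "% covered by retained partners)\n",
      sep = "")
  print(x$table, digits = 3)
  invisible(x)
}

#' Dissimilarity between breeds from their connection profiles
#'
#' Correlation variant: `d(i, j) = 1 - r(row_i, row_j)` with the self cells of
#' both breeds excluded pairwise; rows without variance give `d = 1` with a
#' warning. Similarity variant: `d(i, j) = 1 - counts(i, j) / max(counts)`.
#'
#' @param x A `connection_matrix` over at least 3 breeds.
#' @param method `"correlation"` or `"similarity"`.
#' @return Symmetric numeric dissimilarity matrix with zero diagonal.
#' @export
profile_distance_matrix <- function(x, method = c("correlation", "similarity")) {
  stopifnot(inherits(x, "connection_matrix"))
  method <- match.arg(method)
  n <- length(x$breeds)
  if (n < 3L) stop("need at least 3 breeds")
  C <- x$counts
  D <- matrix(0, n, n, dimnames = dimnames(C))
  if (method == "similarity") {
    mx <- max(C)
    if (mx == 0) stop("connection matrix is all zero")
    D <- 1 - C / mx
    diag(D) <- 0
    return(D)
  }
  warned <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- setdiff(seq_len(n), c(i, j))
    ri <- C[i, keep]; rj <- C[j, keep]
    si <- stats::sd(ri); sj <- stats::sd(rj)
    if (length(keep) < 2L || is.na(si) || is.na(sj) || si == 0 || sj == 0) {
      D[i, j] <- D[j, i] <- 1
      warned <- TRUE
    } else {
      D[i, j] <- D[j, i] <- 1 - stats::cor(ri, rj)
    }
  }
  if (warned) warning("constant profile row(s): correlation undefined, distance set to 1")
  D
}
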