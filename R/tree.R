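#' Parse a Newick string into a phylogenetic tree
#'
#' Thin, validating wrapper around [ape::read.tree()]: tip names and branch
#' lengths are preserved, polytomies are kept as-is, and duplicate tip labels
#' or unbalanced parentheses are rejected with the offending position.
#'
#' @param text A Newick string terminated by `;`.
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text)) stop("Newick string lacks a terminating ';'")
  chars <- strsplit(text, "")[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop("unbalanced parentheses at character ", which(depth < 0)[1L])
  if (depth[length(depth)] != 0)
    stop("unbalanced parentheses: ", depth[length(depth)],
         " unclosed '(' at end of string")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip name: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  tr
}

#' Write a tree as a Newick string or file
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL, digits = 10L) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Transition (`A<->G`, `C<->T`) and transversion proportions P and Q are
#' computed over positions where both sequences carry a resolved base
#' (pairwise deletion), then
#' `d = 1/2 log(1/(1 - 2P - Q)) + 1/4 log(1/(1 - 2Q))` substitutions/site.
#'
#' @param s1,s2 Aligned sequence strings of equal length.
#' @param min_shared Minimum number of shared resolved sites required.
#' @return Distance in substitutions per site.
#' @export
k2p_distance <- function(s1, s2, min_shared = 0L) {
  if (nchar(s1) != nchar(s2)) stop("sequences are not the same length")
  a <- strsplit(s1, "")[[1L]]
  b <- strsplit(s2, "")[[1L]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n < max(1L, min_shared))
    stop("only ", n, " shared resolved sites (minimum ", min_shared, ")")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturation: K2P distance undefined for P = ", P, ", Q = ", Q)
  0.5 * log(1 / w1) + 0.25 * log(1 / w2)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Pairs sharing fewer than `min_shared` resolved sites are rejected, a guard
#' against spuriously short distances between fragments of disjoint coverage.
#'
#' @param aln Named character vector of aligned sequences.
#' @param min_shared Minimum shared resolved sites per pair (default 50).
#' @return Symmetric numeric matrix of distances.
#' @export
k2p_matrix <- function(aln, min_shared = 50L) {
  n <- length(aln)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  if (n < 2L) return(D)
  m <- aln_matrix(aln)
  resolved <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  purine <- matrix(m %in% c("A", "G"), nrow = n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- resolved[i, ] & resolved[j, ]
    ns <- sum(ok)
    if (ns < max(1L, min_shared))
      stop("sequences ", names(aln)[i], " and ", names(aln)[j], " share only ",
           ns, " resolved sites (minimum ", min_shared, ")")
    diff <- ok & (m[i, ] != m[j, ])
    ts <- diff & (purine[i, ] == purine[j, ])
    P <- sum(ts) / ns
    Q <- (sum(diff) - sum(ts)) / ns
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0)
      stop("saturation between ", names(aln)[i], " and ", names(aln)[j],
           ": K2P distance undefined (P = ", P, ", Q = ", Q, ")")
    D[i, j] <- D[j, i] <- 0.5 * log(1 / w1) + 0.25 * log(1 / w2)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining via [ape::nj()]; the returned tree is the
#' unrooted topology represented with its root node at the final amalgamation.
#' A desk-scale surrogate for an external maximum-likelihood search.
#'
#' @param D Symmetric distance matrix with zero diagonal, n >= 3.
#' @return A `phylo` object.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  ape::nj(stats::as.dist(D))
}

#' Root a tree on the edge separating an outgroup
#'
#' The root is placed on the branch separating the outgroup tips from the
#' rest, and that branch's length is split evenly between the two root edges.
#' An outgroup that does not form one side of a split of the unrooted tree is
#' an error.
#'
#' @param tree A `phylo` object.
#' @param outgroup_ids Tip labels of the outgroup.
#' @return A rooted `phylo` object.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  missing_og <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing_og))
    stop("outgroup tip(s) absent from tree: ", paste(missing_og, collapse = ", "))
  if (length(setdiff(tree$tip.label, outgroup_ids)) == 0L)
    stop("outgroup cannot contain every tip")
  utree <- ape::unroot(tree)
  rooted <- tryCatch(
    ape::root(utree, outgroup = outgroup_ids, resolve.root = TRUE),
    error = function(e)
      stop("outgroup is not monophyletic on the unrooted tree; offending tips: ",
           paste(outgroup_ids, collapse = ", "), call. = FALSE)
  )
  # split the attachment edge evenly between the two root children
  if (!is.null(rooted$edge.length)) {
    root_node <- ape::Ntip(rooted) + 1L
    kid_edges <- which(rooted$edge[, 1L] == root_node)
    if (length(kid_edges) == 2L) {
      tot <- sum(rooted$edge.length[kid_edges])
      rooted$edge.length[kid_edges] <- tot / 2
    }
  }
  rooted
}

tip_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1L]]]
}

#' Assign tips to maternal haplogroups by clade placement
#'
#' Each query tip receives the haplogroup of the smallest ancestral clade that
#' contains at least one reference tip, provided all references in that clade
#' agree; otherwise the tip falls back to the nearest reference by patristic
#' distance (flagged in the `method` column). Reference tips keep their own
#' label.
#'
#' @param tree Rooted `phylo` over queries and references.
#' @param reference_labels Named character vector `id -> haplogroup`, or a
#'   data.frame with columns `id` and `haplogroup`.
#' @return Data.frame of class `haplogroup_assignment` with columns `id`,
#'   `haplogroup`, `method` (`reference`, `clade` or `nearest`).
#' @export
assign_haplogroups <- function(tree, reference_labels) {
  if (is.data.frame(reference_labels))
    reference_labels <- stats::setNames(as.character(reference_labels$haplogroup),
                                        reference_labels$id)
  refs <- names(reference_labels)
  if (length(refs) == 0L) stop("no reference labels supplied")
  missing_ref <- setdiff(refs, tree$tip.label)
  if (length(missing_ref))
    stop("reference tip(s) absent from tree: ", paste(missing_ref, collapse = ", "))

  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  clade_tips <- phangorn::Descendants(tree, (ntip + 1L):(ntip + tree$Nnode), "tips")
  is_ref <- tree$tip.label %in% refs
  ref_hg_of_tip <- reference_labels[tree$tip.label]
  patristic <- NULL

  out <- data.frame(id = tree$tip.label,
                    haplogroup = NA_character_,
                    method = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ntip)) {
    if (is_ref[i]) {
      out$haplogroup[i] <- unname(reference_labels[tree$tip.label[i]])
      out$method[i] <- "reference"
      next
    }
    node <- parent[i]
    assigned <- FALSE
    while (node != 0L) {
      tips_here <- clade_tips[[node - ntip]]
      hg <- unique(stats::na.omit(ref_hg_of_tip[tips_here]))
      if (length(hg) == 1L) {
        out$haplogroup[i] <- hg
        out$method[i] <- "clade"
        assigned <- TRUE
        break
      }
      if (length(hg) > 1L) break  # mosaic clade: fall back to distance
      node <- parent[node]
    }
    if (!assigned) {
      if (is.null(tree$edge.length))
        stop("patristic fallback needed for tip ", tree$tip.label[i],
             " but the tree has no branch lengths")
      if (is.null(patristic)) patristic <- stats::cophenetic(tree)
      d <- patristic[tree$tip.label[i], refs]
      nearest <- refs[order(d, refs)][1L]
      out$haplogroup[i] <- unname(reference_labels[nearest])
      out$method[i] <- "nearest"
    }
  }
  class(out) <- c("haplogroup_assignment", "data.frame")
  out
}
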