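test_that("type-1 pairs are the cherries of the tree", {
  tr <- parse_newick("((A1,B1),(C1,(D1,E1)));")
  expect_identical(sorted_rows(unname(find_type1_pairs(tr))),
                   sorted_rows(rbind(c("A1", "B1"), c("D1", "E1"))))

  # polytomy generalization: all tip pairs under the node, with a message
  expect_message(p3 <- find_type1_pairs(parse_newick("(A1,B1,C1);")),
                 "polytomy")
  expect_identical(nrow(p3), 3L)

  # mixed polytomy: the (C,F) tip pair under the multifurcation plus the
  # (D,E) cherry
  expect_identical(nrow(suppressMessages(
    find_type1_pairs(parse_newick("(A,(B,(C,(D,E),F)));")))), 2L)
})

test_that("type-2 triples are tips sister to an embedded cherry", {
  tr <- parse_newick("((A1,B1),(C1,(D1,E1)));")
  expect_identical(unname(find_type2_triples(tr)),
                   rbind(c("C1", "D1", "E1")))

  # B1 is sister to the (A1,A2) cherry; C1's sister is not a cherry
  tr2 <- parse_newick("(((A1,A2),B1),C1);")
  expect_identical(unname(find_type2_triples(tr2)),
                   rbind(c("B1", "A1", "A2")))

  tr3 <- parse_newick("((A1,B1),C1);")
  expect_identical(unname(find_type2_triples(tr3)),
                   rbind(c("C1", "A1", "B1")))
})

test_that("connection counts match exhaustive pattern enumeration on random trees", {
  set.seed(101)
  for (i in 1:25) {
    tr <- random_binary_tree(sample(5:100, 1), seed = 1000 + i)
    bt <- random_breeds(tr, n_breeds = sample(2:6, 1))
    tb <- stats::setNames(bt$breed, bt$id)

    m1 <- connection_matrix(tr, bt, 1)
    expect_identical(m1$counts, oracle_breed_counts(oracle_type1(tr), tb))

    m2 <- connection_matrix(tr, bt, 2)
    tri <- oracle_type2(tr)
    links <- rbind(tri[, c(1, 2), drop = FALSE], tri[, c(1, 3), drop = FALSE])
    expect_identical(m2$counts, oracle_breed_counts(links, tb))

    # structural invariants
    expect_identical(m1$counts, t(m1$counts))
    ut <- upper.tri(m1$counts, diag = TRUE)
    expect_identical(sum(m1$counts[ut]), nrow(oracle_type1(tr)))
    expect_identical(sum(m2$counts[upper.tri(m2$counts, diag = TRUE)]),
                     2L * nrow(tri))
  }
})

test_that("connection matrices are invariant to ladderization and within-breed relabeling", {
  tr <- random_binary_tree(40, seed = 9)
  bt <- local({ set.seed(2); random_breeds(tr, 4) })
  left <- connection_matrix(ape::ladderize(tr, right = FALSE), bt, 2)
  right <- connection_matrix(ape::ladderize(tr, right = TRUE), bt, 2)
  expect_identical(left$counts, right$counts)

  # permute ids within one breed
  bt2 <- bt
  ids <- bt$id[bt$breed == bt$breed[1]]
  perm <- stats::setNames(sample(ids), ids)
  tr2 <- tr
  tr2$tip.label <- ifelse(tr$tip.label %in% ids, perm[tr$tip.label], tr$tip.label)
  relabeled <- connection_matrix(tr2, bt, 2)
  expect_identical(relabeled$counts, connection_matrix(tr, bt, 2)$counts)
})

test_that("connection_matrix resolves every tip or fails loudly", {
  tr <- parse_newick("((A1,B1),C1);")
  bt <- make_breed_table(c("A1", "B1", "C1"), c("AAAA", "BBBB", "CCCC"))
  cm <- connection_matrix(tr, bt, 1)
  expect_identical(cm$counts["AAAA", "BBBB"], 1L)
  expect_identical(sum(cm$counts), 2L)  # the mirrored cell only
  expect_error(connection_matrix(tr, bt[-2, ], 1), "B1")
})

test_that("breed profiles rank, convert to percent and truncate by retention", {
  counts <- matrix(c(0L, 3L, 1L, 0L,
                     3L, 2L, 0L, 1L,
                     1L, 0L, 0L, 4L,
                     0L, 1L, 4L, 5L), 4, 4, byrow = TRUE,
                   dimnames = list(c("FOCL", "XXXX", "YYYY", "ZZZZ"),
                                   c("FOCL", "XXXX", "YYYY", "ZZZZ")))
  cm <- structure(list(breeds = rownames(counts), counts = counts,
                       kinship_type = 2L, n_links = 99L),
                  class = "connection_matrix")
  # single partner -> 100%
  p1 <- breed_profile(cm, "YYYY", include_self = FALSE)
  expect_equal(p1$table$percent[p1$table$partner == "ZZZZ"], 80)

  # counts {X:3, Y:1}, retention 0.75 -> X retained alone at 75%
  p2 <- breed_profile(cm, "FOCL", retention_fraction = 0.75)
  expect_identical(p2$table$retained, c(TRUE, FALSE))
  expect_equal(p2$retained_fraction, 0.75)
  expect_equal(sum(p2$table$percent), 100)

  # grouping merges partners before percentages
  p3 <- breed_profile(cm, "FOCL", grouping = c(XXXX = "GRP", YYYY = "GRP"))
  expect_identical(p3$table$partner, "GRP")
  expect_equal(p3$table$percent, 100)

  expect_error(breed_profile(cm, "none"), "focal")
})

test_that("profile distances match direct formula evaluation", {
  counts <- matrix(c(0L, 5L, 2L, 1L,
                     5L, 0L, 3L, 2L,
                     2L, 3L, 0L, 8L,
                     1L, 2L, 8L, 0L), 4, 4, byrow = TRUE,
                   dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  cm <- structure(list(breeds = LETTERS[1:4], counts = counts,
                       kinship_type = 2L, n_links = 21L),
                  class = "connection_matrix")
  Dc <- profile_distance_matrix(cm, "correlation")
  for (i in 1:3) for (j in (i + 1):4) {
    keep <- setdiff(1:4, c(i, j))
    expect_equal(Dc[i, j], 1 - stats::cor(counts[i, keep], counts[j, keep]),
                 tolerance = 1e-12)
  }
  Ds <- profile_distance_matrix(cm, "similarity")
  expect_equal(Ds["C", "D"], 0)        # the maximal count
  expect_equal(Ds["A", "D"], 1 - 1 / 8)
  expect_equal(diag(Ds), rep(0, 4), ignore_attr = TRUE)

  # identical rows -> distance 0; anti-correlated -> 2
  counts2 <- counts; counts2[2, ] <- counts2[1, ]; counts2[, 2] <- counts2[, 1]
  cm2 <- structure(list(breeds = LETTERS[1:4], counts = counts2,
                        kinship_type = 2L, n_links = 0L),
                   class = "connection_matrix")
  expect_equal(suppressWarnings(
    profile_distance_matrix(cm2, "correlation"))["A", "B"], 0,
    tolerance = 1e-12)
})
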