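test_that("Newick parsing preserves tips, lengths and polytomies", {
  tr <- parse_newick("((A,B),C);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))

  tr2 <- parse_newick("(A:1,B:2):0;")
  expect_equal(sort(tr2$edge.length), c(1, 2))

  tr3 <- parse_newick("((A,B,C),D);")
  root_kids <- tabulate(tr3$edge[, 1])
  expect_true(3 %in% root_kids)  # degree-3 polytomy preserved
})

test_that("Newick parsing rejects malformed input with a position", {
  expect_error(parse_newick("((A,B),C)"), ";")
  expect_error(parse_newick("((A,B),C));"), "character 10")
  expect_error(parse_newick("(((A,B),C;"), "unclosed")
  expect_error(parse_newick("((A,B),A);"), "duplicate")
})

test_that("Newick round-trips preserve topology and branch lengths", {
  set.seed(3)
  for (i in 1:5) {
    tr <- random_binary_tree(sample(4:20, 1), seed = i)
    back <- parse_newick(write_newick(tr))
    expect_equal(phangorn::RF.dist(tr, back), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  }
})

test_that("K2P distance follows the closed form", {
  expect_identical(k2p_distance("ACGTACGT", "ACGTACGT"), 0)
  # 8 sites, 2 transitions: P = 0.25, Q = 0 -> 0.5 log 2 = 0.3466
  expect_equal(k2p_distance("AAAAAAAA", "GGAAAAAA"), 0.5 * log(2),
               tolerance = 1e-12)
  expect_equal(round(k2p_distance("AAAAAAAA", "GGAAAAAA"), 4), 0.3466)
  # P = 0.5, Q = 0 drives the transition log argument to zero
  expect_error(k2p_distance("AAAAAAAA", "GGGGAAAA"), "saturation")
  # pairwise deletion: the N column is ignored
  expect_equal(k2p_distance("NAAAAAAAA", "GGGAAAAAA"),
               k2p_distance("AAAAAAAA", "GGAAAAAA"), tolerance = 1e-12)
  expect_error(k2p_distance("ACGT", "ACGT", min_shared = 50), "shared")
})

test_that("K2P dominates the p-distance and agrees with it as p -> 0", {
  set.seed(21)
  for (i in 1:20) {
    s1 <- random_seqs(1, 500)[[1]]
    a <- strsplit(s1, "")[[1]]
    nmut <- sample(1:40, 1)
    pos <- sample(500, nmut)
    b <- a
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
    s2 <- paste(b, collapse = "")
    pdist <- mean(a != b)
    expect_gte(k2p_distance(s1, s2) + 1e-12, pdist)
    if (pdist <= 0.01)
      expect_lt(abs(k2p_distance(s1, s2) - pdist), 1e-3)
  }
  # explicit first-order case
  s1 <- paste(rep("A", 1000), collapse = "")
  s2 <- paste(c(rep("G", 5), rep("A", 995)), collapse = "")
  expect_lt(abs(k2p_distance(s1, s2) - 0.005), 1e-3)
})

test_that("neighbor joining recovers additive trees and is deterministic", {
  tr3 <- nj_tree(matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
                        dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  expect_equal(ape::Ntip(tr3), 3)

  true4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  D <- ape::cophenetic.phylo(true4)
  # four-point condition picks the AB|CD split
  expect_lt(D["A", "B"] + D["C", "D"],
            min(D["A", "C"] + D["B", "D"], D["A", "D"] + D["B", "C"]))
  njt <- nj_tree(D[c("B", "D", "A", "C"), c("B", "D", "A", "C")])
  expect_equal(phangorn::RF.dist(ape::unroot(njt), ape::unroot(true4)), 0)

  # ties: identical calls give identical output
  Dt <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4])); diag(Dt) <- 0
  expect_identical(write_newick(nj_tree(Dt)), write_newick(nj_tree(Dt)))

  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("outgroup rooting places the root on the outgroup edge, split evenly", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,O:2):1);")
  r <- root_with_outgroup(tr, "O")
  ntip <- ape::Ntip(r)
  kids <- r$edge[r$edge[, 1] == ntip + 1, 2]
  expect_true(which(r$tip.label == "O") %in% kids)  # O sister to all else
  root_lens <- r$edge.length[r$edge[, 1] == ntip + 1]
  expect_equal(root_lens[1], root_lens[2])  # even split
  expect_equal(sum(root_lens), 2)           # O's pendant edge length preserved

  # idempotence on an already-correctly-rooted tree
  r2 <- root_with_outgroup(r, "O")
  expect_equal(phangorn::RF.dist(r, r2), 0)

  expect_error(root_with_outgroup(parse_newick("((A,O1),((B,O2),C));"),
                                  c("O1", "O2")), "monophyletic")
  expect_error(root_with_outgroup(tr, "nope"), "absent")
})

test_that("haplogroup assignment follows the smallest labeled clade", {
  tr <- parse_newick("(((q1:1,refB:1):1,(q2:1,q3:1):1):1,(refA:1,q4:1):2);")
  refs <- c(refB = "B", refA = "A")
  hg <- assign_haplogroups(tr, refs)
  lab <- stats::setNames(hg$haplogroup, hg$id)
  expect_identical(lab[["q1"]], "B")   # in a cherry with the B reference
  expect_identical(lab[["q4"]], "A")
  expect_identical(lab[["refB"]], "B") # reference keeps its own label
  expect_identical(lab[["q2"]], "B")   # smallest labeled ancestral clade
  meth <- stats::setNames(hg$method, hg$id)
  expect_identical(meth[["refA"]], "reference")
  expect_identical(meth[["q1"]], "clade")
})

test_that("mosaic clades fall back to the nearest reference by patristic distance", {
  # q1's smallest labeled clade contains both references -> fallback
  tr <- parse_newick("((refA:1,refB:4):1,q1:1.5);")
  hg <- assign_haplogroups(tr, c(refA = "A", refB = "B"))
  lab <- stats::setNames(hg$haplogroup, hg$id)
  expect_identical(lab[["q1"]], "A")  # 3.5 to refA vs 6.5 to refB
  expect_identical(hg$method[hg$id == "q1"], "nearest")

  # topology-only tree cannot do the fallback
  tr2 <- parse_newick("((refA,refB),q1);")
  expect_error(assign_haplogroups(tr2, c(refA = "A", refB = "B")),
               "branch lengths")
  expect_error(assign_haplogroups(tr, c(refX = "A")), "absent")
})

test_that("haplogroup assignment depends on position, not the query label", {
  tr <- parse_newick("(((q1:1,refB:1):1,(q2:1,q3:1):1):1,(refA:1,q4:1):2);")
  refs <- c(refB = "B", refA = "A")
  base <- assign_haplogroups(tr, refs)
  tr2 <- tr
  tr2$tip.label[tr2$tip.label == "q1"] <- "zz9"
  renamed <- assign_haplogroups(tr2, refs)
  expect_identical(renamed$haplogroup[renamed$id == "zz9"],
                   base$haplogroup[base$id == "q1"])
  expect_identical(renamed$haplogroup[renamed$id != "zz9"],
                   base$haplogroup[base$id != "q1"])
})
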