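test_that("pairwise_identity handles gaps and degenerate overlap", {
  expect_equal(pairwise_identity("ACDEF", "ACDEF"), 100)
  expect_equal(pairwise_identity("AAAAAAAAAA", "AAAAAAAAAC"), 90)
  expect_equal(pairwise_identity("--A", "A--"), 0)
  expect_equal(pairwise_identity("A-CD", "A-CE"), 100 * 2 / 3)
  expect_error(pairwise_identity("AC", "A"), class = "rtt_parameter_error")
})

test_that("distance_matrix computes p-distances with fallbacks", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "CCAAAAAAAA")
  d <- distance_matrix(aln)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.2)
  expect_true(isSymmetric(d))
  expect_error(distance_matrix(aln[1:2]), class = "rtt_parameter_error")
  # zero comparable columns: distance = max observed + 0.1, with a warning
  aln2 <- c(a = "AA--", b = "--AA", c = "AAAA", d = "ATAA")
  expect_warning(d2 <- distance_matrix(aln2), "zero comparable")
  # max observed distance is d(a,d) = 0.5 (one mismatch in two columns)
  expect_equal(unname(d2["a", "b"]), 0.5 + 0.1)
  # Poisson correction flag
  dp <- distance_matrix(aln, correction = "poisson")
  expect_equal(dp["a", "c"], -log(1 - 0.2))
})

test_that("nj_tree matches the three-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3), tolerance = 1e-12)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "rtt_parameter_error")
  asym <- d; asym[1, 2] <- 3
  expect_error(nj_tree(asym), class = "rtt_parameter_error")
})

test_that("nj_tree recovers a hand-built additive four-taxon matrix", {
  # tree ((A:1,B:1):1,(C:1,D:1):1): path lengths by hand
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  # split AB|CD present
  key <- retrotether:::canonical_split(c("A", "B"), lab)
  expect_true(key %in% retrotether:::tree_bipartitions(tr))
  # exact path lengths reproduced
  co <- ape::cophenetic.phylo(tr)[lab, lab]
  expect_equal(unname(co), unname(d), tolerance = 1e-9)
  # identical taxa form a zero-length cherry
  d0 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(lab[1:3], lab[1:3]))
  tr0 <- nj_tree(d0)
  blen <- tr0$edge.length[tr0$edge[, 2] %in% match(c("A", "B"), tr0$tip.label)]
  expect_equal(blen, c(0, 0), tolerance = 1e-12)
})

test_that("nj_tree reproduces random additive topologies exactly", {
  for (i in 1:20) {
    tr <- random_additive(6, seed = 700 + i)
    d <- ape::cophenetic.phylo(tr)
    got <- nj_tree(d)
    co <- ape::cophenetic.phylo(got)[rownames(d), colnames(d)]
    expect_equal(unname(co), unname(d), tolerance = 1e-9)
  }
})

test_that("bootstrap_support finds a planted split and is deterministic", {
  sim <- two_clade_alignment(n_per = 4, len = 120, seed = 3)
  tr <- bootstrap_support(sim$aln, n_reps = 100, seed = 5)
  mono <- test_monophyly(tr, sim$clade1)
  expect_true(mono$monophyletic)
  expect_gte(mono$support, 95)
  tr2 <- bootstrap_support(sim$aln, n_reps = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  # single replicate: supports are 0 or 100
  tr1 <- bootstrap_support(sim$aln, n_reps = 1, seed = 2)
  supp <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(supp[!is.na(supp)] %in% c(0, 100)))
  expect_error(bootstrap_support(sim$aln, n_reps = 0, seed = 1),
               class = "rtt_parameter_error")
})

test_that("credible_clusters applies an inclusive threshold", {
  tr <- ape::read.tree(text = "(((A:1,B:1)x:1,(C:1,D:1)y:1)z:1,(E:1,F:1)w:1)r;")
  nl <- tr$node.label  # assign supports by node name, not by internal order
  tr$node.label <- unname(c(r = "", z = "94", x = "95", y = "96",
                            w = "100")[nl])
  cl <- credible_clusters(tr, threshold = 95)
  keys <- vapply(cl, paste, character(1), collapse = "|")
  expect_length(cl, 3)  # 95, 96 and 100 qualify; 94 does not
  expect_true("A|B" %in% keys && "C|D" %in% keys && "E|F" %in% keys)
  # star tree has no internal edges, hence no clusters
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1)r;")
  star$node.label <- ""
  expect_length(credible_clusters(star), 0)
  # all supports 100: every non-trivial bipartition is returned
  tr$node.label <- ifelse(nl == "r", "", "100")
  expect_length(credible_clusters(tr), 4)
})

test_that("test_monophyly reads bipartitions exactly", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(test_monophyly(tr, c("A", "B"))$monophyletic)
  expect_false(test_monophyly(ape::read.tree(text = "((A,C),(B,D));"),
                              c("A", "B"))$monophyletic)
  expect_error(test_monophyly(tr, c("A", "Q")),
               class = "rtt_parameter_error")
  expect_error(test_monophyly(tr, c("A", "B", "C", "D")),
               class = "rtt_parameter_error")
})

test_that("concat_alignment intersects ids and records the partition", {
  a1 <- c(A = "MKL", B = "MKV", C = "MRL")
  a2 <- c(B = "DEAD", C = "DEAE", D = "DDDD")
  cc <- concat_alignment(a1, a2)
  expect_setequal(names(cc), c("B", "C"))
  expect_equal(nchar(cc[["B"]]), 7)
  expect_identical(cc[["B"]], "MKVDEAD")
  expect_equal(attr(cc, "partition"), 3)
  expect_error(concat_alignment(a1, c(Z = "AA")),
               class = "rtt_parameter_error")
})

test_that("progressive_align produces sensible deterministic alignments", {
  two <- progressive_align(c(x = "MKLVDE", y = "MKLVDE"))
  expect_identical(unname(two), c("MKLVDE", "MKLVDE"))
  al <- progressive_align(c(x = "ACDEFG", y = "ACEFG"))
  expect_identical(unname(al[["x"]]), "ACDEFG")
  expect_identical(unname(al[["y"]]), "AC-EFG")
  withr::with_seed(8, {
    seqs <- setNames(vapply(1:6, function(i)
      paste(sample(retrotether:::AA20, sample(40:70, 1), TRUE),
            collapse = ""), character(1)), paste0("s", 1:6))
    msa <- progressive_align(seqs)
    expect_length(unique(nchar(msa)), 1)
    expect_gte(nchar(msa[[1]]), max(nchar(seqs)))
    expect_identical(msa, progressive_align(seqs))
    # degapped rows reproduce the inputs
    expect_identical(gsub("-", "", msa[names(seqs)]), seqs)
  })
  expect_error(progressive_align(c(a = "MK")), class = "rtt_parameter_error")
})

test_that("a family diverged from one ancestor aligns nearly gap-free", {
  withr::with_seed(12, {
    anc <- paste(sample(retrotether:::AA20, 100, TRUE), collapse = "")
    fam <- setNames(vapply(1:5, function(i)
      retrotether:::.mutate_protein(anc, 0.1), character(1)),
      paste0("f", 1:5))
    msa <- progressive_align(fam)
    # substitutions only: at most a couple of spurious gap columns
    expect_lte(nchar(msa[[1]]), 104)
    d <- distance_matrix(msa)
    expect_true(all(d[upper.tri(d)] < 0.25))
  })
})

test_that("filter_lineages implements the two-of-three rule and is monotone", {
  combos <- expand.grid(c1 = c(FALSE, TRUE), c2 = c(FALSE, TRUE),
                        c3 = c(FALSE, TRUE))
  flags <- data.frame(lineage = sprintf("L%d", 1:8),
                      c1_discordant_clustering = combos$c1,
                      c2_unique_structure = combos$c2,
                      c3_whole_contig_or_no_ltr = combos$c3)
  res <- filter_lineages(flags)
  expect_identical(res$flags$removed,
                   rowSums(combos) >= 2)
  # monotonicity: flipping any FALSE flag to TRUE never un-removes
  for (i in 1:8) for (col in 2:4) {
    if (!flags[i, col]) {
      f2 <- flags
      f2[i, col] <- TRUE
      r2 <- filter_lineages(f2)
      if (res$flags$removed[i]) expect_true(r2$flags$removed[i])
    }
  }
})

test_that("lineage_flags derives the three criteria", {
  lineages <- data.frame(
    lineage = c("L1", "L2", "L3", "L4"),
    taxon_group = c("g1", "g1", "g2", "g2"),
    structure = c("S1", "S1", "S2", "S1"),
    whole_contig_or_no_ltr = c(FALSE, FALSE, TRUE, FALSE))
  clusters <- list(c("L1", "L2"), c("L2", "L3"))
  fl <- lineage_flags(lineages, clusters)
  expect_identical(fl$c1_discordant_clustering, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(fl$c2_unique_structure, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(fl$c3_whole_contig_or_no_ltr, c(FALSE, FALSE, TRUE, FALSE))
  res <- filter_lineages(fl)
  expect_identical(res$removed, "L3")  # meets criteria 1, 2 and 3
  expect_true("L4" %in% res$retained)  # only criterion 1
})

test_that("fitch_parsimony counts minimal changes", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  all_same <- fitch_parsimony(tr, list(a = "S1", b = "S1", c = "S1", d = "S1"))
  expect_equal(all_same$changes, 0)
  split2 <- fitch_parsimony(tr, list(a = "S1", b = "S1", c = "S2", d = "S2"))
  expect_equal(split2$changes, 1)
  expect_error(fitch_parsimony(tr, list(a = "S1", b = "S1", c = "S2")),
               class = "rtt_parameter_error")
  expect_error(
    fitch_parsimony(ape::read.tree(text = "(a,b,(c,d));"),
                    list(a = "S1", b = "S1", c = "S2", d = "S2")),
    class = "rtt_parameter_error")
  # polymorphic tips can absorb a change
  poly <- fitch_parsimony(tr, list(a = "S1", b = c("S1", "S2"),
                                   c = "S2", d = "S2"))
  expect_equal(poly$changes, 1)
})

test_that("fitch_parsimony equals the exhaustive oracle on random cases", {
  labels <- c("S1", "S2", "S4")
  for (i in 1:20) {
    withr::with_seed(800 + i, {
      n <- sample(4:6, 1)
      tr <- ape::rtree(n)
      states <- setNames(lapply(seq_len(n), function(j)
        sample(labels, sample(1:2, 1))), tr$tip.label)
    })
    got <- fitch_parsimony(tr, states)
    expect_equal(got$changes, fitch_oracle(tr, states))
  }
})
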