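test_that("Fitch length matches hand-countable cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  same <- matrix("G", 4, 5, dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(fitch_length(tr, same), 0)
  one <- cbind(A = "A", B = "A", C = "R", D = "R")
  expect_equal(fitch_length(tr, t(one)), 1)
  # grouping mismatched pairs costs two changes
  tr2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(fitch_length(tr2, t(one)), 2)
  # leaf/taxa mismatch
  expect_error(fitch_length(tr, t(cbind(A = "A", B = "A", C = "R", E = "R"))),
               "differ")
})

test_that("Fitch equals the brute-force assignment oracle", {
  for (s in 1:10) {
    mat <- random_aa_matrix(6, 30, n_states = 4, seed = s)
    tr <- ape::unroot(ape::rtree(6, tip.label = rownames(mat)))
    expect_equal(fitch_length(tr, mat), fitch_oracle(tr, mat), info = s)
  }
})

test_that("Fitch agrees with the reference parsimony implementation", {
  skip_if_not_installed("phangorn")
  for (s in 1:5) {
    mat <- random_aa_matrix(7, 40, n_states = 5, seed = 100 + s)
    tr <- ape::unroot(ape::rtree(7, tip.label = rownames(mat)))
    pd <- phangorn::phyDat(mat, type = "AA")
    expect_equal(fitch_length(tr, mat),
                 as.numeric(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("Fitch is invariant to leaf order, rooting, and missing sites", {
  mat <- random_aa_matrix(6, 25, n_states = 4, seed = 7)
  tr <- ape::unroot(ape::rtree(6, tip.label = rownames(mat)))
  base <- fitch_length(tr, mat)
  expect_equal(fitch_length(tr, mat[sample(rownames(mat)), ]), base)
  rerooted <- ape::root(tr, outgroup = "t3", resolve.root = TRUE)
  expect_equal(fitch_length(rerooted, mat), base)
  # an all-missing column contributes nothing
  aug <- cbind(mat, rep("X", 6), rep("-", 6))
  expect_equal(fitch_length(tr, aug), base)
})

test_that("four-taxon search returns the topology favoured by the data", {
  mat <- rbind(A = rep(c("G", "A"), c(5, 5)),
               B = rep(c("G", "A"), c(5, 5)),
               C = rep(c("R", "D"), c(5, 5)),
               D = rep(c("R", "D"), c(5, 5)))
  res <- search_mp_trees(mat, mode = "exhaustive")
  expect_equal(res$n_evaluated, 3L)  # (2n-5)!! for n = 4
  expect_length(res$trees, 1L)
  expect_identical(tree_splits(res$trees[[1]]), "C|D")
  expect_error(search_mp_trees(mat[1:3, , drop = FALSE]), "4 to 12")
})

test_that("branch-and-bound returns the identical minimal set as enumeration", {
  for (s in 1:10) {
    mat <- random_aa_matrix(7, 12, n_states = 3, seed = 200 + s)
    ex <- search_mp_trees(mat, mode = "exhaustive")
    bb <- search_mp_trees(mat, mode = "branch_and_bound")
    expect_equal(bb$score, ex$score, info = s)
    expect_setequal(sapply(bb$trees, topo_signature),
                    sapply(ex$trees, topo_signature))
    expect_equal(ex$n_evaluated, 945L)  # (2*7-5)!!
  }
})

test_that("simulated alignments recover the generating topology", {
  tree <- ape::read.tree(
    text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  tree$edge.length <- tree$edge.length * 0.1
  mat <- simulate_alignment(tree, 2000, subst_rate = 1, seed = 10)
  res <- search_mp_trees(mat, mode = "branch_and_bound")
  expect_length(res$trees, 1L)
  expect_identical(topo_signature(res$trees[[1]]),
                   topo_signature(ape::unroot(tree)))
})

test_that("rate zero gives identical sequences and zero tree length", {
  tree <- ape::rtree(6)
  mat <- simulate_alignment(tree, 50, subst_rate = 0, seed = 3)
  expect_equal(length(unique(apply(mat, 1, paste, collapse = ""))), 1L)
  expect_equal(fitch_length(ape::unroot(tree), mat), 0)
})

test_that("majority-rule consensus contains exactly the majority splits", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_identical(topo_signature(majority_rule_consensus(list(t1, t1, t1))),
                   topo_signature(t1))
  all100 <- majority_rule_consensus(list(t1, t1))
  expect_true(all(as.numeric(all100$node.label[nzchar(all100$node.label)]) ==
                    100))
  # a split in 2 of 3 trees appears with 66.7% support
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  cons <- majority_rule_consensus(list(t1, t1, t2))
  expect_setequal(tree_splits(cons), tree_splits(t1))
  sup <- as.numeric(cons$node.label[nzchar(cons$node.label)])
  expect_equal(sup, rep(66.7, length(tree_splits(t1))), tolerance = 0.1)
  # exactly-half splits are excluded (strict majority)
  half <- majority_rule_consensus(list(t1, t2))
  expect_length(tree_splits(half), 0L)
  expect_error(majority_rule_consensus(list(
    t1, ape::read.tree(text = "((A,B),(C,E),F);"))), "mismatch")
})

test_that("consensus splits are pairwise compatible for random inputs", {
  compatible <- function(a, b, taxa) {
    A <- strsplit(a, "|", fixed = TRUE)[[1]]
    B <- strsplit(b, "|", fixed = TRUE)[[1]]
    all(A %in% B) || all(B %in% A) || !length(intersect(A, B))
  }
  set.seed(31)
  for (rep in 1:5) {
    trees <- lapply(1:7, function(i) ape::rtree(8, tip.label = paste0("t", 1:8)))
    cons <- majority_rule_consensus(trees, threshold = 0.3)
    sp <- tree_splits(cons)
    if (length(sp) > 1)
      for (i in seq_along(sp)[-1]) for (j in 1:(i - 1))
        expect_true(compatible(sp[i], sp[j]))
  }
})

test_that("consensus topology agrees with the reference implementation", {
  set.seed(17)
  trees <- c(lapply(1:6, function(i) ape::rtree(7, tip.label = paste0("t", 1:7))))
  ours <- majority_rule_consensus(trees)
  ref <- ape::consensus(trees, p = 0.5 + 1e-9)
  expect_setequal(tree_splits(ours), tree_splits(ref))
})

test_that("bootstrap supports are deterministic and saturate on clean data", {
  tree <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):1);")
  tree$edge.length <- tree$edge.length * 0.15
  mat <- simulate_alignment(tree, 400, subst_rate = 1, seed = 5)
  b1 <- bootstrap_support(mat, n_replicates = 30, seed = 9)
  b2 <- bootstrap_support(mat, n_replicates = 30, seed = 9)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  expect_identical(topo_signature(b1), topo_signature(ape::unroot(tree)))
  sup <- as.numeric(b1$node.label[nzchar(b1$node.label)])
  expect_true(all(sup >= 90))
  expect_error(bootstrap_support(mat, n_replicates = 0), ">= 1")
})

test_that("NEXUS export carries the matrix and partition blocks", {
  d1 <- concatenation_scheme("dataset1")
  seqs <- list(
    A = list(COL1A1 = strrep("G", 1057), COL1A2 = strrep("A", 1041)),
    B = list(COL1A1 = strrep("G", 1057), COL1A2 = strrep("P", 1041)))
  aln <- concatenate_dataset(seqs, d1)
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus(aln, path)
  txt <- readLines(path)
  expect_true(any(grepl("NTAX=2 NCHAR=2098", txt)))
  expect_true(any(grepl("CHARSET COL1A2 = 1058-2098", txt)))
})
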