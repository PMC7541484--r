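test_that("substitution authentication follows the three acceptance rules", {
  grid <- expand.grid(depth = 1:3, has_b = c(TRUE, FALSE),
                      has_y = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_identical(
      authenticate_substitution(g$depth, g$has_b, g$has_y),
      g$depth >= 2 && g$has_b && g$has_y,
      info = sprintf("depth=%d b=%s y=%s", g$depth, g$has_b, g$has_y))
  }
  # hydroxyproline-alanine vs proline-serine needs hydroxyl localization
  expect_true(authenticate_substitution(3, TRUE, TRUE,
                                        hydroxyproline_ambiguous = TRUE,
                                        hydroxyl_supported = TRUE))
  expect_false(authenticate_substitution(3, TRUE, TRUE,
                                         hydroxyproline_ambiguous = TRUE,
                                         hydroxyl_supported = FALSE))
  expect_false(authenticate_substitution(3, TRUE, TRUE,
                                         hydroxyproline_ambiguous = TRUE,
                                         hydroxyl_supported = NA))
})

test_that("consensus equals the reference for concordant full coverage", {
  ref <- "GAPGVKGAPGERGAPGPAGK"
  cc <- call_consensus(gen_consensus_psms(ref, depth = 2), ref)
  expect_equal(cc$sequence, ref)
  expect_equal(cc$coverage, 100)
  expect_error(call_consensus(gen_consensus_psms(ref)[0, ], ref), "empty")
})

test_that("planted variants are called iff they pass authentication", {
  ref <- "GAPGVKGAPGERGAPGPAGK"
  tru <- "GAPGVRGAPGERGAPGPAGK"  # K6R substitution
  ok <- call_consensus(gen_consensus_psms(ref, tru, depth = 3), ref)
  expect_equal(substr(ok$sequence, 6, 6), "R")
  # depth 1: rejected, called X
  low <- call_consensus(gen_consensus_psms(ref, tru, depth = 1), ref)
  expect_equal(substr(low$sequence, 6, 6), "X")
  # depth 3 but missing b-ion support: rejected
  nob <- call_consensus(gen_consensus_psms(ref, tru, depth = 3, has_b = FALSE),
                        ref)
  expect_equal(substr(nob$sequence, 6, 6), "X")
})

test_that("deamidation-coupled variants are held for review, not called", {
  ref <- "GAPGNKGAPGQRGAPGPAGK"
  tru <- "GAPGDKGAPGERGAPGPAGK"  # N->D and Q->E: deamidation chemistry
  cc <- call_consensus(gen_consensus_psms(ref, tru, depth = 4), ref)
  expect_equal(substr(cc$sequence, 5, 5), "X")
  expect_equal(substr(cc$sequence, 11, 11), "X")
  expect_setequal(cc$review$pos, c(5, 11))
})

test_that("uncovered regions are X and reduce coverage proportionally", {
  ref <- strrep("GAPGVK", 10)  # 60 sites
  gap <- 25:36                 # 20% of positions uncovered
  cc <- call_consensus(gen_consensus_psms(ref, uncovered = gap,
                                          peptide_length = 6), ref)
  expect_equal(cc$coverage, 80, tolerance = 1)
  expect_true(all(strsplit(cc$sequence, "")[[1]][gap] == "X"))
})

test_that("leucine-isoleucine conversion is total and idempotent", {
  expect_equal(finalize_sequence("GLPGLK"), "GIPGIK")
  expect_equal(finalize_sequence("GIPGAK"), "GIPGAK")
  expect_equal(finalize_sequence(finalize_sequence("GLPGLK")),
               finalize_sequence("GLPGLK"))
  expect_equal(nchar(finalize_sequence("LLLL")), 4L)
})

test_that("concatenation schemes have the published segment structure", {
  d1 <- concatenation_scheme("dataset1")
  expect_equal(sum(d1$length), 2098L)
  expect_equal(d1$length, c(1057L, 1041L))
  d2 <- concatenation_scheme("dataset2")
  expect_equal(sum(d2$length), 5003L)
  expect_equal(d2$length[-(1:2)],
               c(364L, 359L, 416L, 303L, 472L, 372L, 202L, 417L))
  # contiguous, non-overlapping, starting at 1
  expect_equal(d2$start[1], 1L)
  expect_equal(d2$start[-1], d2$end[-nrow(d2)] + 1L)
})

test_that("dataset concatenation yields the expected alignment lengths", {
  mk <- function(scheme, taxa = c("A", "B", "C")) {
    seqs <- lapply(taxa, function(tx) {
      s <- lapply(scheme$length, function(n) strrep("G", n))
      names(s) <- scheme$protein
      s
    })
    names(seqs) <- taxa
    seqs
  }
  d1 <- concatenation_scheme("dataset1")
  a1 <- concatenate_dataset(mk(d1), d1)
  expect_equal(unique(nchar(a1$sequences)), 2098L)
  d2 <- concatenation_scheme("dataset2")
  a2 <- concatenate_dataset(mk(d2), d2)
  expect_equal(unique(nchar(a2$sequences)), 5003L)
  # missing protein: X-padded with a warning
  seqs <- mk(d2)
  seqs$A$SERPINF1 <- NULL
  expect_warning(a3 <- concatenate_dataset(seqs, d2), "missing protein")
  expect_equal(unname(substr(a3$sequences["A"], 4587, 5003)),
               strrep("X", 417))
  # wrong segment length: error naming taxon and protein
  seqs2 <- mk(d1)
  seqs2$B$COL1A2 <- strrep("G", 999)
  expect_error(concatenate_dataset(seqs2, d1), "taxon B protein COL1A2")
})

test_that("alignments round-trip through FASTA with partitions", {
  d1 <- concatenation_scheme("dataset1")
  seqs <- lapply(c(tax1 = 1, tax2 = 2), function(i) {
    s <- lapply(d1$length, function(n)
      paste(sample(c("G", "A", "P", "X"), n, replace = TRUE), collapse = ""))
    names(s) <- d1$protein
    s
  })
  aln <- concatenate_dataset(seqs, d1)
  fa <- withr::local_tempfile(fileext = ".fasta")
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_concat_alignment(aln, fa, pt)
  mat <- read_alignment_fasta(fa)
  expect_equal(dim(mat), c(2L, 2098L))
  expect_equal(paste(mat["tax1", ], collapse = ""), aln$sequences[["tax1"]])
  parts <- read.delim(pt)
  expect_equal(parts$end[2], 2098L)
})
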