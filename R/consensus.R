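# Consensus protein-sequence calling from PSM evidence and assembly of the
# concatenated phylogenetic datasets.
#
# A site is called as the reference residue when covered and concordant, as an
# authenticated variant when the substitution evidence passes the acceptance
# rules (>= 2 PSMs, both b and y fragment ions, and hydroxyproline placement
# for the isobaric hydroxyproline-alanine / proline-serine ambiguity), and as
# 'X' (missing sequence) when uncovered or uncertain.

#' Authenticate a proposed amino-acid substitution
#'
#' Accepted iff the variant is supported by at least `min_depth`
#' peptide-spectrum matches AND both b- and y-ion series are present AND,
#' when the call is the isobaric hydroxyproline-alanine versus proline-serine
#' ambiguity, the hydroxyl localization supports it.
#'
#' @param depth Number of PSMs supporting the variant.
#' @param has_b,has_y Presence of b-/y-ion support among those PSMs.
#' @param hydroxyproline_ambiguous Is the call the Hyp-Ala vs Pro-Ser
#'   isobaric pair?
#' @param hydroxyl_supported For ambiguous calls: does the hydroxyl
#'   localization support the variant?
#' @param min_depth Minimum PSM depth (default 2).
#' @return Logical: accepted?
#' @export
authenticate_substitution <- function(depth, has_b, has_y,
                                      hydroxyproline_ambiguous = FALSE,
                                      hydroxyl_supported = NA,
                                      min_depth = 2L) {
  ok <- depth >= min_depth && isTRUE(has_b) && isTRUE(has_y)
  if (ok && isTRUE(hydroxyproline_ambiguous))
    ok <- isTRUE(hydroxyl_supported)
  isTRUE(ok)
}

# Hyp-Ala vs Pro-Ser: hydroxyproline + alanine is isobaric with proline +
# serine, so an S<->A exchange adjacent to a proline cannot be distinguished
# from a hydroxylation shift without localizing the hydroxyl.
.is_hyp_ambiguous <- function(ref_res, var_res, prev_ref) {
  (identical(prev_ref, "P")) &&
    ((ref_res == "A" && var_res == "S") || (ref_res == "S" && var_res == "A"))
}

#' Call a consensus sequence from PSM evidence
#'
#' Per reference position: the reference residue when covered and concordant;
#' an authenticated variant when [authenticate_substitution()] accepts it;
#' otherwise `X`. Variants co-occurring with deamidation chemistry (D at a
#' reference N, E at a reference Q) are never auto-accepted: they are called
#' `X` and listed for manual review. When two different variants each pass
#' authentication at one site, the higher summed PSM intensity wins; an exact
#' tie gives `X`.
#'
#' @param psms PSM data frame with columns `protein_id`, `peptide`,
#'   `protein_start`, `ion_intensity`, `has_b`, `has_y` and optionally
#'   `hydroxyl_supported`.
#' @param reference Reference mature-chain sequence (string).
#' @param protein_id Optional filter on `psms$protein_id`.
#' @param min_depth Minimum variant PSM depth (default 2).
#' @return A `consensus_sequence`: list with `protein_id`, `sequence`,
#'   `per_site_support` (data frame: `pos`, `ref`, `call`, `depth`,
#'   `variant_depth`), `coverage` (percent non-X), `review` (data frame of
#'   deamidation-coupled variants held for manual review).
#' @export
call_consensus <- function(psms, reference, protein_id = NULL, min_depth = 2L) {
  if (!is.null(protein_id))
    psms <- psms[psms$protein_id == protein_id, , drop = FALSE]
  if (!nrow(psms)) stop("empty PSM table")
  if (is.null(psms$hydroxyl_supported)) psms$hydroxyl_supported <- NA
  n <- nchar(reference)
  ref <- strsplit(reference, "")[[1]]
  calls <- vector("list", n)
  for (i in seq_len(nrow(psms))) {
    s <- psms$protein_start[i]
    pep <- strsplit(psms$peptide[i], "")[[1]]
    for (k in seq_along(pep)) {
      pos <- s + k - 1L
      if (pos < 1L || pos > n) next
      calls[[pos]][[length(calls[[pos]]) + 1L]] <-
        list(res = pep[k], intensity = psms$ion_intensity[i],
             has_b = isTRUE(psms$has_b[i]), has_y = isTRUE(psms$has_y[i]),
             hydroxyl = psms$hydroxyl_supported[i])
    }
  }
  out <- character(n)
  support <- data.frame(pos = seq_len(n), ref = ref, call = NA_character_,
                        depth = 0L, variant_depth = 0L)
  review <- list()
  for (pos in seq_len(n)) {
    obs <- calls[[pos]]
    if (!length(obs)) { out[pos] <- "X"; support$call[pos] <- "X"; next }
    res <- vapply(obs, `[[`, "", "res")
    support$depth[pos] <- length(res)
    variants <- setdiff(unique(res), ref[pos])
    if (!length(variants)) {
      out[pos] <- ref[pos]; support$call[pos] <- ref[pos]; next
    }
    accepted <- list()
    flagged_review <- FALSE
    for (v in variants) {
      sel <- obs[res == v]
      vdepth <- length(sel)
      support$variant_depth[pos] <- max(support$variant_depth[pos], vdepth)
      # deamidation-coupled exchange: held for manual review, never auto-called
      if ((ref[pos] == "N" && v == "D") || (ref[pos] == "Q" && v == "E")) {
        flagged_review <- TRUE
        review[[length(review) + 1L]] <- data.frame(
          pos = pos, ref = ref[pos], variant = v, depth = vdepth)
        next
      }
      amb <- .is_hyp_ambiguous(ref[pos], v, if (pos > 1) ref[pos - 1] else "")
      hyd <- any(vapply(sel, function(o) isTRUE(o$hydroxyl), TRUE))
      ok <- authenticate_substitution(
        depth = vdepth,
        has_b = any(vapply(sel, `[[`, TRUE, "has_b")),
        has_y = any(vapply(sel, `[[`, TRUE, "has_y")),
        hydroxyproline_ambiguous = amb,
        hydroxyl_supported = if (amb) hyd else NA,
        min_depth = min_depth)
      if (ok)
        accepted[[v]] <- sum(vapply(sel, `[[`, 0, "intensity"))
    }
    if (length(accepted) == 1L) {
      out[pos] <- names(accepted)
    } else if (length(accepted) > 1L) {
      ints <- unlist(accepted)
      best <- which(ints == max(ints))
      out[pos] <- if (length(best) == 1L) names(ints)[best] else "X"
    } else {
      out[pos] <- "X"  # variant evidence present but unauthenticated
    }
    support$call[pos] <- out[pos]
  }
  structure(list(
    protein_id = if (is.null(protein_id)) psms$protein_id[1] else protein_id,
    sequence = paste(out, collapse = ""),
    per_site_support = support,
    coverage = 100 * mean(out != "X"),
    review = if (length(review)) do.call(rbind, review)
             else data.frame(pos = integer(), ref = character(),
                             variant = character(), depth = integer())),
    class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("<consensus_sequence> %s: %d sites, coverage %.1f%%\n",
              x$protein_id, nchar(x$sequence), x$coverage))
  invisible(x)
}

#' Convert leucines to isoleucines
#'
#' L and I are isobaric and indistinguishable by low-energy tandem MS, so
#' every L is replaced by I before phylogenetic comparison. Idempotent; no
#' other residue is touched and the length is unchanged.
#'
#' @param seq A `consensus_sequence` or plain string.
#' @return Same type as the input.
#' @export
finalize_sequence <- function(seq) {
  if (inherits(seq, "consensus_sequence")) {
    seq$sequence <- gsub("L", "I", seq$sequence, fixed = TRUE)
    return(seq)
  }
  gsub("L", "I", seq, fixed = TRUE)
}

.SCHEME_D1 <- data.frame(
  protein = c("COL1A1", "COL1A2"),
  start = c(1L, 1058L),
  end = c(1057L, 2098L))

.SCHEME_D2 <- rbind(.SCHEME_D1, data.frame(
  protein = c("AHSG", "CHAD", "OMD", "SPARC", "VTN", "BGN", "CLEC3B",
              "SERPINF1"),
  start = c(2099L, 2463L, 2822L, 3238L, 3541L, 4013L, 4385L, 4587L),
  end   = c(2462L, 2821L, 3237L, 3540L, 4012L, 4384L, 4586L, 5003L)))

#' Concatenation scheme for the phylogenetic datasets
#'
#' Dataset 1 is mature type I collagen only (COL1A1 positions 1-1057, COL1A2
#' 1058-2098, total 2098). Dataset 2 appends eight non-collagenous bone
#' proteins (AHSG, CHAD, OMD, SPARC, VTN, BGN, CLEC3B, SERPINF1) for a total
#' of 5003 positions. Ranges are 1-based inclusive, contiguous and
#' non-overlapping.
#'
#' @param dataset `"dataset1"` or `"dataset2"`.
#' @return A `concat_scheme`: data frame with columns `protein`, `start`,
#'   `end`, `length`.
#' @export
concatenation_scheme <- function(dataset = c("dataset1", "dataset2")) {
  dataset <- match.arg(dataset)
  sch <- if (dataset == "dataset1") .SCHEME_D1 else .SCHEME_D2
  sch$length <- sch$end - sch$start + 1L
  structure(sch, class = c("concat_scheme", "data.frame"),
            dataset = dataset)
}

#' Concatenate per-protein sequences into an alignment
#'
#' Rows are per-taxon concatenations in scheme order; each protein segment
#' must match the scheme's segment length exactly (sequences are assumed
#' pre-aligned on a common mature-chain coordinate system). A protein missing
#' for a taxon is padded with `X` and a warning is raised; a wrong-length
#' segment is an error naming the taxon and protein.
#'
#' @param sequences Named list (taxa) of named lists (proteins) of sequence
#'   strings or `consensus_sequence` objects.
#' @param scheme A [concatenation_scheme()].
#' @return A `concat_alignment`: list with `taxa`, `sequences` (named
#'   character vector), `partitions` (the scheme).
#' @export
concatenate_dataset <- function(sequences, scheme = concatenation_scheme()) {
  stopifnot(inherits(scheme, "concat_scheme"))
  taxa <- names(sequences)
  if (is.null(taxa) || any(!nzchar(taxa))) stop("sequences must be named by taxon")
  rows <- vapply(taxa, function(tx) {
    segs <- vapply(seq_len(nrow(scheme)), function(i) {
      prot <- scheme$protein[i]
      want <- scheme$length[i]
      s <- sequences[[tx]][[prot]]
      if (is.null(s)) {
        warning(sprintf("taxon %s missing protein %s: padded with X", tx, prot))
        return(strrep("X", want))
      }
      if (inherits(s, "consensus_sequence")) s <- s$sequence
      if (nchar(s) != want)
        stop(sprintf("length mismatch for taxon %s protein %s: %d != %d",
                     tx, prot, nchar(s), want))
      s
    }, "")
    paste(segs, collapse = "")
  }, "")
  structure(list(taxa = taxa, sequences = rows, partitions = scheme),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment> %d taxa x %d positions (%s)\n",
              length(x$taxa), nchar(x$sequences[1]),
              attr(x$partitions, "dataset")))
  invisible(x)
}

#' Character matrix view of a concatenated alignment
#'
#' @param alignment A `concat_alignment` (or named character vector of
#'   equal-length sequences).
#' @return Character matrix, taxa x sites.
#' @export
as_character_matrix <- function(alignment) {
  seqs <- if (inherits(alignment, "concat_alignment")) alignment$sequences
          else alignment
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  mat <- t(vapply(seqs, function(s) strsplit(s, "")[[1]],
                  character(lens[1])))
  rownames(mat) <- names(seqs)
  mat
}

#' Write an alignment and its partition table
#'
#' FASTA via Biostrings plus a TSV with one row per protein segment
#' (`protein`, `start`, `end`).
#'
#' @param alignment A `concat_alignment`.
#' @param fasta_path,partition_path Output paths (`NULL` to skip one).
#' @export
write_concat_alignment <- function(alignment, fasta_path,
                                   partition_path = NULL) {
  stopifnot(inherits(alignment, "concat_alignment"))
  aa <- Biostrings::AAStringSet(alignment$sequences)
  Biostrings::writeXStringSet(aa, fasta_path)
  if (!is.null(partition_path)) {
    utils::write.table(
      alignment$partitions[, c("protein", "start", "end")],
      partition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Read an alignment FASTA as a character matrix
#'
#' @param path FASTA path.
#' @return Character matrix, taxa x sites.
#' @export
read_alignment_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- names(aa)
  as_character_matrix(seqs)
}
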