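# Monoisotopic atomic masses (CODATA/IUPAC) and isotope abundances used for
# peptide mass arithmetic and isotope-envelope prediction. Six or more decimals
# are required so that published MALDI calibration m/z values are reproduced to
# four decimal places.
.ATOMIC_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                  O = 15.9949146196, S = 31.97207100)

.PROTON_MASS <- 1.00727646688
.WATER_MASS <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]

# Average spacing between adjacent peptide isotopologue peaks.
.ISOTOPE_SPACING <- 1.00336

# Isotope abundance vectors indexed by nucleon offset 0, 1, 2, ... from the
# lightest isotope (IUPAC 2021 representative values).
.ISOTOPE_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0001)
)

# Residue (amino acid minus water) elemental compositions, 20-letter alphabet.
# L and I share a composition; B/Z/X are rejected as they denote ambiguity or
# missing sequence, not a chemical entity.
.RESIDUE_COMPOSITION <- local({
  tab <- rbind(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
  )
  colnames(tab) <- c("C", "H", "N", "O", "S")
  tab
})

# Elemental deltas of the supported variable modifications.
# Oxidation/hydroxylation add one oxygen; deamidation (N->D, Q->E) swaps an
# amide NH2 for a hydroxyl: net -N -H +O (= +0.984016 Da).
.MOD_DELTA <- list(
  oxidation_M      = c(C = 0, H = 0, N = 0, O = 1, S = 0),
  hydroxylation_PK = c(C = 0, H = 0, N = 0, O = 1, S = 0),
  deamidation_NQ   = c(C = 0, H = -1, N = -1, O = 1, S = 0)
)

# Residues each modification type may sit on.
.MOD_TARGETS <- list(
  oxidation_M = "M",
  hydroxylation_PK = c("P", "K"),
  deamidation_NQ = c("N", "Q")
)

#' Deamidation monoisotopic mass increment
#'
#' Mass added when an asparagine or glutamine side-chain amide is hydrolysed to
#' the corresponding acid (N to D, Q to E): one oxygen replaces NH,
#' approximately +0.98402 Da.
#'
#' @return Mass increment in Da.
#' @export
deamidation_mass <- function() {
  unname(.ATOMIC_MASS["O"] - .ATOMIC_MASS["N"] - .ATOMIC_MASS["H"])
}

#' Construct a peptide
#'
#' A peptide is an uppercase amino-acid string over the 20-letter alphabet plus
#' an optional list of variable modifications. Supported modification types are
#' `oxidation_M`, `hydroxylation_PK` and `deamidation_NQ`; each must sit on a
#' chemically valid residue.
#'
#' @param sequence Uppercase amino-acid string. Ambiguity codes (B, Z, X) are
#'   rejected: X marks missing sequence downstream, not a residue.
#' @param modifications Optional data frame with columns `type` and `position`
#'   (1-based), or a list of `list(type=, position=)` entries.
#' @return An object of class `peptide`.
#' @examples
#' p1105 <- peptide("GVQGPPGPAGPR",
#'                  modifications = data.frame(type = "hydroxylation_PK",
#'                                             position = 6))
#' monoisotopic_mh(p1105)
#' @export
peptide <- function(sequence, modifications = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters, rownames(.RESIDUE_COMPOSITION))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  mods <- .normalize_mods(modifications)
  if (nrow(mods)) {
    if (any(mods$position < 1L | mods$position > length(letters)))
      stop("modification position outside sequence")
    for (i in seq_len(nrow(mods))) {
      ty <- mods$type[i]
      if (!ty %in% names(.MOD_DELTA))
        stop("unknown modification type: ", ty)
      res <- letters[mods$position[i]]
      if (!res %in% .MOD_TARGETS[[ty]])
        stop(sprintf("modification %s not valid on residue %s at position %d",
                     ty, res, mods$position[i]))
    }
  }
  structure(list(sequence = sequence, modifications = mods),
            class = "peptide")
}

.normalize_mods <- function(modifications) {
  if (is.null(modifications))
    return(data.frame(type = character(), position = integer()))
  if (is.data.frame(modifications)) {
    stopifnot(all(c("type", "position") %in% names(modifications)))
    return(data.frame(type = as.character(modifications$type),
                      position = as.integer(modifications$position)))
  }
  if (is.list(modifications)) {
    return(data.frame(
      type = vapply(modifications, function(m) as.character(m$type), ""),
      position = vapply(modifications, function(m) as.integer(m$position), 1L)
    ))
  }
  stop("modifications must be NULL, a data frame or a list")
}

.as_peptide <- function(x) {
  if (inherits(x, "peptide")) x else peptide(x)
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide>", x$sequence, "\n")
  if (nrow(x$modifications)) {
    cat("  modifications:",
        paste(sprintf("%s@%d", x$modifications$type, x$modifications$position),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Elemental composition of a peptide
#'
#' Sums residue compositions, adds one water for the termini and applies the
#' elemental deltas of any modifications.
#'
#' @param peptide A [peptide()] or plain sequence string.
#' @return Named integer-valued vector with elements C, H, N, O, S.
#' @export
elemental_composition <- function(peptide) {
  pep <- .as_peptide(peptide)
  letters <- strsplit(pep$sequence, "")[[1]]
  comp <- colSums(.RESIDUE_COMPOSITION[letters, , drop = FALSE])
  comp["H"] <- comp["H"] + 2  # water
  comp["O"] <- comp["O"] + 1
  if (nrow(pep$modifications)) {
    for (ty in pep$modifications$type) comp <- comp + .MOD_DELTA[[ty]]
  }
  comp
}

#' Singly protonated monoisotopic mass [M+H]+
#'
#' Monoisotopic peptide mass (residues + water + modification increments) plus
#' one proton. Reproduces the standard MALDI calibration values, e.g.
#' bradykinin 1-7 (RPPGFSP) at m/z 757.3992.
#'
#' @param peptide A [peptide()] or plain sequence string.
#' @return \[M+H\]+ in Da.
#' @export
monoisotopic_mh <- function(peptide) {
  comp <- elemental_composition(peptide)
  unname(sum(comp * .ATOMIC_MASS[names(comp)]) + .PROTON_MASS)
}

#' Theoretical isotope distribution of a peptide
#'
#' Relative abundances of the first `n_peaks` isotopologues, obtained by
#' convolving the isotope polynomials of the peptide's elemental composition
#' (exponentiation by squaring per element), then truncating and normalizing
#' to unit sum.
#'
#' @param peptide A [peptide()] or sequence string.
#' @param n_peaks Number of isotopologue peaks to return (>= 2).
#' @return An `isotope_distribution`: list with `base_mz` (monoisotopic
#'   \[M+H\]+), `relative_intensities` (sums to 1) and `spacing` (Da).
#' @export
isotope_distribution <- function(peptide, n_peaks = 6L) {
  n_peaks <- as.integer(n_peaks)
  if (n_peaks < 2L) stop("n_peaks must be >= 2")
  comp <- elemental_composition(peptide)
  dist <- .composition_isotope_pattern(comp, n_peaks)
  structure(list(base_mz = monoisotopic_mh(peptide),
                 relative_intensities = dist / sum(dist),
                 spacing = .ISOTOPE_SPACING),
            class = "isotope_distribution")
}

# Isotope pattern (relative to the all-light isotopologue) for an elemental
# composition, truncated to n_peaks nucleon offsets.
.composition_isotope_pattern <- function(comp, n_peaks) {
  out <- 1
  for (el in names(comp)) {
    n <- comp[[el]]
    if (n <= 0) next
    out <- .convolve_trunc(out, .poly_power(.ISOTOPE_ABUNDANCE[[el]], n, n_peaks),
                           n_peaks)
  }
  length(out) <- n_peaks
  out[is.na(out)] <- 0
  out
}

.convolve_trunc <- function(a, b, n) {
  m <- min(n, length(a) + length(b) - 1L)
  out <- numeric(m)
  for (i in seq_along(a)) {
    jmax <- min(length(b), m - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# p(x)^n truncated to n_terms coefficients, by squaring.
.poly_power <- function(p, n, n_terms) {
  result <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) result <- .convolve_trunc(result, base, n_terms)
    n <- n %/% 2
    if (n > 0) base <- .convolve_trunc(base, base, n_terms)
  }
  result
}

#' @export
print.isotope_distribution <- function(x, ...) {
  cat("<isotope_distribution> base m/z", sprintf("%.4f", x$base_mz),
      " spacing", x$spacing, "\n")
  cat("  intensities:", paste(sprintf("%.4f", x$relative_intensities),
                              collapse = " "), "\n")
  invisible(x)
}

#' Add a deamidation to a peptide
#'
#' Marks the N or Q at `site` as deamidated; the \[M+H\]+ increases by the
#' deamidation increment (+0.98402 Da).
#'
#' @param peptide A [peptide()] or sequence string.
#' @param site 1-based position; the residue there must be N or Q.
#' @return The modified `peptide`.
#' @export
apply_deamidation <- function(peptide, site) {
  pep <- .as_peptide(peptide)
  site <- as.integer(site)
  letters <- strsplit(pep$sequence, "")[[1]]
  if (site < 1L || site > length(letters))
    stop("site outside sequence")
  if (!letters[site] %in% c("N", "Q"))
    stop(sprintf("residue at site %d is %s, not N or Q", site, letters[site]))
  mods <- rbind(pep$modifications,
                data.frame(type = "deamidation_NQ", position = site))
  peptide(pep$sequence, modifications = mods)
}
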