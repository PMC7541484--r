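# Diagenetic prescreening of bone/dentine: FTIR crystallinity and collagen
# indices plus elemental C:N, with the screening thresholds used to judge
# whether a sample is worth destructive collagen extraction.

# Band-search windows (cm^-1) bracketing the canonical bone bands:
# phosphate nu4 doublet (~605, ~565) with its valley (~590), phosphate nu3
# (~1010) and amide I (~1640). Baselines are drawn between the minima of the
# flanking windows.
.IR_WINDOWS <- list(
  nu4a    = c(595, 615),
  nu4b    = c(555, 575),
  valley  = c(580, 600),
  nu4_flank_lo = c(525, 545),
  nu4_flank_hi = c(625, 650),
  nu3     = c(990, 1040),
  nu3_flank_lo = c(900, 990),
  nu3_flank_hi = c(1040, 1140),
  amide1  = c(1600, 1680),
  amide1_flank_lo = c(1500, 1600),
  amide1_flank_hi = c(1680, 1780)
)

.IR_EPS <- 1e-8

#' Construct an infrared spectrum
#'
#' @param wavenumbers Strictly monotone wavenumber grid in cm^-1.
#' @param absorbance Absorbance values, same length.
#' @return An object of class `ir_spectrum` (stored in ascending wavenumber).
#' @export
ir_spectrum <- function(wavenumbers, absorbance) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance) || length(wavenumbers) < 2L)
    stop("wavenumbers and absorbance must have equal length >= 2")
  d <- diff(wavenumbers)
  if (all(d < 0)) {  # store ascending
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (!all(d > 0)) {
    stop("wavenumbers must be strictly monotone")
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.0f-%.0f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Read / write two-column spectrum text
#'
#' Whitespace-delimited wavenumber/absorbance pairs, the common instrument
#' text-export layout.
#'
#' @param path File path.
#' @return [read_ir_spectrum()] returns an `ir_spectrum`.
#' @export
read_ir_spectrum <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("wavenumber", "absorbance"))
  ir_spectrum(tab$wavenumber, tab$absorbance)
}

#' @param spectrum An `ir_spectrum`.
#' @rdname read_ir_spectrum
#' @export
write_ir_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  utils::write.table(
    data.frame(wavenumber = sprintf("%.4f", spectrum$wavenumbers),
               absorbance = sprintf("%.6e", spectrum$absorbance)),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.ir_window_values <- function(spectrum, window) {
  sel <- spectrum$wavenumbers >= window[1] & spectrum$wavenumbers <= window[2]
  if (!any(sel)) stop(sprintf("spectrum does not cover %g-%g cm^-1",
                              window[1], window[2]))
  list(x = spectrum$wavenumbers[sel], y = spectrum$absorbance[sel])
}

# Height of the extremum within `window` above the straight line joining the
# minima of the two flanking windows. `what` selects max (peak) or min (valley).
.baseline_corrected_height <- function(spectrum, window, flank_lo, flank_hi,
                                       what = c("max", "min")) {
  what <- match.arg(what)
  lo <- .ir_window_values(spectrum, flank_lo)
  hi <- .ir_window_values(spectrum, flank_hi)
  x0 <- lo$x[which.min(lo$y)]; y0 <- min(lo$y)
  x1 <- hi$x[which.min(hi$y)]; y1 <- min(hi$y)
  w <- .ir_window_values(spectrum, window)
  corrected <- w$y - (y0 + (y1 - y0) * (w$x - x0) / (x1 - x0))
  if (what == "max") max(corrected) else min(corrected)
}

#' Infrared splitting factor (IRSF)
#'
#' Crystallinity index of bioapatite: the summed baseline-corrected heights of
#' the phosphate nu4 doublet (~605 and ~565 cm^-1) divided by the height of the
#' valley between them (~590 cm^-1). Higher values indicate larger, more
#' ordered crystals, i.e. stronger diagenetic recrystallization. Invariant to
#' additive baseline offsets and to uniform intensity scaling.
#'
#' @param spectrum An `ir_spectrum` covering at least 525-650 cm^-1.
#' @return IRSF (unitless, > 0).
#' @export
compute_irsf <- function(spectrum) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  h605 <- .baseline_corrected_height(spectrum, .IR_WINDOWS$nu4a,
                                     .IR_WINDOWS$nu4_flank_lo,
                                     .IR_WINDOWS$nu4_flank_hi)
  h565 <- .baseline_corrected_height(spectrum, .IR_WINDOWS$nu4b,
                                     .IR_WINDOWS$nu4_flank_lo,
                                     .IR_WINDOWS$nu4_flank_hi)
  scale_ref <- max(abs(spectrum$absorbance) - min(abs(spectrum$absorbance)),
                   .IR_EPS)
  if (h605 <= .IR_EPS * scale_ref || h565 <= .IR_EPS * scale_ref)
    stop("degenerate spectrum: phosphate nu4 doublet not detectable")
  hval <- .baseline_corrected_height(spectrum, .IR_WINDOWS$valley,
                                     .IR_WINDOWS$nu4_flank_lo,
                                     .IR_WINDOWS$nu4_flank_hi, what = "min")
  if (hval <= .IR_EPS * scale_ref)
    stop("degenerate spectrum: nu4 valley height not positive")
  (h605 + h565) / hval
}

#' Amide-to-phosphate ratio (Am/P)
#'
#' Relative content of collagen versus mineral apatite: baseline-corrected
#' amide I height (~1640 cm^-1) over phosphate nu3 height (~1010 cm^-1).
#'
#' @param spectrum An `ir_spectrum` covering 900-1780 cm^-1.
#' @return Am/P (unitless, >= 0).
#' @export
compute_amp <- function(spectrum) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  hp <- .baseline_corrected_height(spectrum, .IR_WINDOWS$nu3,
                                   .IR_WINDOWS$nu3_flank_lo,
                                   .IR_WINDOWS$nu3_flank_hi)
  scale_ref <- max(abs(spectrum$absorbance) - min(abs(spectrum$absorbance)),
                   .IR_EPS)
  if (hp <= .IR_EPS * scale_ref)
    stop("degenerate spectrum: phosphate nu3 band absent")
  ha <- .baseline_corrected_height(spectrum, .IR_WINDOWS$amide1,
                                   .IR_WINDOWS$amide1_flank_lo,
                                   .IR_WINDOWS$amide1_flank_hi)
  max(ha, 0) / hp
}

#' Carbon:nitrogen atomic ratio
#'
#' Converts whole-bone weight percentages to an atomic ratio using atomic
#' masses 12.011 (C) and 14.007 (N).
#'
#' @param c_wt Carbon content, weight percent (> 0).
#' @param n_wt Nitrogen content, weight percent (> 0).
#' @return C:N atomic ratio (unitless).
#' @examples
#' cn_atomic_ratio(10.53, 3.37)  # 3.64
#' @export
cn_atomic_ratio <- function(c_wt, n_wt) {
  if (any(c_wt <= 0) || any(n_wt <= 0))
    stop("c_wt and n_wt must be positive")
  (c_wt / 12.011) / (n_wt / 14.007)
}

#' Bundle diagenetic indices
#'
#' @param irsf,am_p,n_wt,c_wt,cn_ratio Index values; `NA` marks not measured.
#'   `cn_ratio` is derived from the weight percentages when both are given.
#' @return An object of class `diagenetic_indices`.
#' @export
diagenetic_indices <- function(irsf = NA_real_, am_p = NA_real_,
                               n_wt = NA_real_, c_wt = NA_real_,
                               cn_ratio = NA_real_) {
  if (is.na(cn_ratio) && !is.na(c_wt) && !is.na(n_wt))
    cn_ratio <- cn_atomic_ratio(c_wt, n_wt)
  structure(list(irsf = irsf, am_p = am_p, n_wt = n_wt, c_wt = c_wt,
                 cn_ratio = cn_ratio),
            class = "diagenetic_indices")
}

#' Screen a sample by its diagenetic indices
#'
#' Applies the standard thresholds: IRSF above 4.0 marks an extremely
#' degraded/burnt bone (`irsf_degraded`); Am/P above 0.07 marks likely
#' successful soluble-collagen extraction (`amp_extractable`); N wt% above 3.0
#' together with C:N between 3.0 and 3.9 marks a sample expected to yield
#' sufficient collagen for radiocarbon dating (`brock_datable`). Missing
#' inputs yield `NA` (not evaluated) for the corresponding flag.
#'
#' @param indices A `diagenetic_indices` object (or arguments forwarded to it).
#' @return Named logical vector with elements `irsf_degraded`,
#'   `amp_extractable`, `brock_datable`; `NA` = not evaluated.
#' @export
screen_sample <- function(indices) {
  if (!inherits(indices, "diagenetic_indices"))
    stop("indices must be a diagenetic_indices object")
  irsf_degraded <- if (is.na(indices$irsf)) NA else indices$irsf > 4.0
  amp_extractable <- if (is.na(indices$am_p)) NA else indices$am_p > 0.07
  brock_datable <-
    if (is.na(indices$n_wt) || is.na(indices$cn_ratio)) NA
    else indices$n_wt > 3.0 && indices$cn_ratio >= 3.0 && indices$cn_ratio <= 3.9
  c(irsf_degraded = irsf_degraded,
    amp_extractable = amp_extractable,
    brock_datable = brock_datable)
}

#' Prescreening report for a set of samples
#'
#' Computes IRSF and Am/P from each sample's spectrum, the C:N ratio from the
#' elemental data, and the screening flags, as one table row per sample.
#'
#' @param samples Named list; each element a list with components `spectrum`
#'   (an `ir_spectrum`, optional) and optional `n_wt`, `c_wt`.
#' @return A data frame with one row per sample.
#' @export
prescreen_report <- function(samples) {
  rows <- lapply(names(samples), function(nm) {
    s <- samples[[nm]]
    irsf <- am_p <- NA_real_
    if (!is.null(s$spectrum)) {
      irsf <- tryCatch(compute_irsf(s$spectrum), error = function(e) NA_real_)
      am_p <- tryCatch(compute_amp(s$spectrum), error = function(e) NA_real_)
    }
    n_wt <- if (is.null(s$n_wt)) NA_real_ else s$n_wt
    c_wt <- if (is.null(s$c_wt)) NA_real_ else s$c_wt
    ind <- diagenetic_indices(irsf = irsf, am_p = am_p, n_wt = n_wt, c_wt = c_wt)
    fl <- screen_sample(ind)
    data.frame(sample = nm, am_p = am_p, irsf = irsf, n_wt = n_wt,
               c_wt = c_wt, cn_ratio = ind$cn_ratio,
               irsf_degraded = fl[["irsf_degraded"]],
               amp_extractable = fl[["amp_extractable"]],
               brock_datable = fl[["brock_datable"]])
  })
  do.call(rbind, rows)
}
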