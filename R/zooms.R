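# ZooMS spectrum processing and deamidation alpha-value estimation.
#
# The alpha-value is the undeamidated fraction of glutamine in a collagen
# marker peptide (1 = pristine, 0 = fully deamidated), estimated by
# non-negative least squares on the overlap of the undeamidated isotope
# envelope with the same envelope shifted by the deamidation increment.

#' Construct a MALDI spectrum
#'
#' @param mz m/z values (Da), strictly increasing.
#' @param intensity Non-negative intensities (counts), same length.
#' @return An object of class `maldi_spectrum`.
#' @export
maldi_spectrum <- function(mz, intensity) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (any(diff(mz) <= 0)) stop("mz must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(mz = mz, intensity = intensity), class = "maldi_spectrum")
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf("<maldi_spectrum> %d points, m/z %.2f-%.2f\n",
              length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Read / write two-column MALDI spectrum text
#'
#' Whitespace-delimited m/z-intensity pairs, the flexAnalysis-style text
#' export.
#'
#' @param path File path.
#' @export
read_maldi_spectrum <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("mz", "intensity"))
  maldi_spectrum(tab$mz, tab$intensity)
}

#' @param spectrum A `maldi_spectrum`.
#' @rdname read_maldi_spectrum
#' @export
write_maldi_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "maldi_spectrum"))
  utils::write.table(
    data.frame(mz = sprintf("%.5f", spectrum$mz),
               intensity = sprintf("%.6e", spectrum$intensity)),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.rolling_stat <- function(x, halfwidth, fun) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    fun(x[max(1, i - halfwidth):min(n, i + halfwidth)]), numeric(1))
}

#' Pick peaks from a raw MALDI spectrum
#'
#' Baseline suppression (rolling-minimum subtraction), smoothing (short
#' moving average), peak detection at local maxima, thresholding at
#' signal-to-noise >= `snr_threshold` and intensity >= `rel_intensity` of the
#' base peak, and optional deisotoping that collapses each isotope envelope
#' onto its monoisotopic member (intensities summed over the envelope).
#'
#' @param raw A `maldi_spectrum` with >= 50 points.
#' @param snr_threshold Minimum signal-to-noise ratio (default 3.5).
#' @param rel_intensity Minimum intensity relative to the base peak
#'   (default 0.005, i.e. 0.5 percent).
#' @param deisotope Collapse isotope envelopes (default TRUE).
#' @param baseline_halfwidth Rolling-minimum half-window in Da.
#' @param smooth_points Moving-average full width in points (odd).
#' @return A `peak_list`: data frame with columns `mz`, `intensity`, `snr`.
#' @export
process_spectrum <- function(raw, snr_threshold = 3.5, rel_intensity = 0.005,
                             deisotope = TRUE, baseline_halfwidth = 1.0,
                             smooth_points = 5L) {
  stopifnot(inherits(raw, "maldi_spectrum"))
  n <- length(raw$mz)
  if (n < 50L) stop("degenerate spectrum: need >= 50 points")
  step <- stats::median(diff(raw$mz))
  bw <- max(1L, round(baseline_halfwidth / step))
  base <- .rolling_stat(raw$intensity, bw, min)
  base <- .rolling_stat(base, bw, mean)  # soften baseline steps
  y <- pmax(raw$intensity - base, 0)
  k <- max(1L, as.integer(smooth_points))
  if (k %% 2 == 0) k <- k + 1L
  sm <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  # robust noise level; peaks occupy few points so the MAD tracks the noise
  noise <- max(stats::mad(sm, na.rm = TRUE), .Machine$double.xmin)
  apex <- which(diff(sign(diff(sm))) < 0) + 1L
  apex <- apex[sm[apex] > 0]
  if (!length(apex))
    return(structure(data.frame(mz = numeric(), intensity = numeric(),
                                snr = numeric()), class = c("peak_list", "data.frame")))
  peaks <- data.frame(mz = raw$mz[apex], intensity = sm[apex],
                      snr = sm[apex] / noise)
  peaks <- peaks[peaks$snr >= snr_threshold, , drop = FALSE]
  if (nrow(peaks))
    peaks <- peaks[peaks$intensity >= rel_intensity * max(peaks$intensity), ,
                   drop = FALSE]
  if (deisotope && nrow(peaks) > 1L) {
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    cluster <- integer(nrow(peaks)); cluster[1] <- 1L
    for (i in 2:nrow(peaks)) {
      gap <- peaks$mz[i] - peaks$mz[i - 1]
      cluster[i] <- if (gap > 0.9 && gap < 1.1) cluster[i - 1] else cluster[i - 1] + 1L
    }
    peaks <- do.call(rbind, lapply(split(peaks, cluster), function(cl)
      data.frame(mz = cl$mz[1], intensity = sum(cl$intensity),
                 snr = max(cl$snr))))
  }
  rownames(peaks) <- NULL
  structure(peaks[order(peaks$mz), , drop = FALSE],
            class = c("peak_list", "data.frame"))
}

#' Average replicate MALDI spectra
#'
#' Pointwise mean intensity on a shared grid. Replicates on identical grids
#' are averaged directly; otherwise they are linearly resampled onto the
#' overlap of their mass ranges.
#'
#' @param spectra List of `maldi_spectrum` objects (>= 1).
#' @return A `maldi_spectrum`.
#' @export
average_replicates <- function(spectra) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "maldi_spectrum")))
  if (length(spectra) == 1L) return(spectra[[1]])
  grids <- lapply(spectra, `[[`, "mz")
  same <- all(vapply(grids[-1], function(g)
    length(g) == length(grids[[1]]) && all(g == grids[[1]]), TRUE))
  if (same) {
    ints <- rowMeans(vapply(spectra, `[[`, numeric(length(grids[[1]])),
                            "intensity"))
    return(maldi_spectrum(grids[[1]], ints))
  }
  lo <- max(vapply(grids, min, 0)); hi <- min(vapply(grids, max, 0))
  if (lo >= hi) stop("incompatible mass ranges: replicates do not overlap")
  grid <- grids[[1]][grids[[1]] >= lo & grids[[1]] <= hi]
  ints <- rowMeans(vapply(spectra, function(s)
    stats::approx(s$mz, s$intensity, xout = grid)$y, numeric(length(grid))))
  maldi_spectrum(grid, ints)
}

#' Default collagen peptide marker table
#'
#' Currently the widely used terrestrial-mammal biomarker at nominal m/z 1105
#' (GVQGPPGPAGPR with hydroxyproline at position 6).
#'
#' @return Data frame with columns `name`, `sequence`, `modifications`
#'   (semicolon-separated `type@pos`), `expected_mz`.
#' @export
zooms_markers <- function() {
  p1105 <- peptide("GVQGPPGPAGPR",
                   modifications = data.frame(type = "hydroxylation_PK",
                                              position = 6L))
  data.frame(name = "P1105", sequence = "GVQGPPGPAGPR",
             modifications = "hydroxylation_PK@6",
             expected_mz = monoisotopic_mh(p1105))
}

.parse_marker_mods <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- strsplit(strsplit(txt, ";")[[1]], "@")
  data.frame(type = vapply(parts, `[`, "", 1),
             position = as.integer(vapply(parts, `[`, "", 2)))
}

#' Match peptide markers against a peak list
#'
#' Nearest-peak assignment within `tol`; an equidistant tie goes to the lower
#' m/z peak; markers without a peak inside the tolerance are reported absent.
#'
#' @param peaks A `peak_list` from [process_spectrum()].
#' @param markers Marker table as in [zooms_markers()]; `expected_mz` is
#'   computed from sequence + modifications when absent.
#' @param tol Match tolerance in Da (default 0.2).
#' @return Data frame with one row per marker: `marker`, `expected_mz`,
#'   `matched`, `mz`, `intensity`, `delta`.
#' @export
match_markers <- function(peaks, markers = zooms_markers(), tol = 0.2) {
  if (is.null(markers$expected_mz)) {
    markers$expected_mz <- vapply(seq_len(nrow(markers)), function(i)
      monoisotopic_mh(peptide(markers$sequence[i],
                              .parse_marker_mods(markers$modifications[i]))),
      0)
  }
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    exp_mz <- markers$expected_mz[i]
    out <- data.frame(marker = markers$name[i], expected_mz = exp_mz,
                      matched = FALSE, mz = NA_real_, intensity = NA_real_,
                      delta = NA_real_)
    if (nrow(peaks)) {
      d <- abs(peaks$mz - exp_mz)
      ok <- which(d <= tol)
      if (length(ok)) {
        best <- ok[order(d[ok], peaks$mz[ok])][1]  # tie -> lower m/z
        out$matched <- TRUE
        out$mz <- peaks$mz[best]
        out$intensity <- peaks$intensity[best]
        out$delta <- peaks$mz[best] - exp_mz
      }
    }
    out
  })
  do.call(rbind, rows)
}

# Exact non-negative least squares for two columns: the unconstrained normal
# equations when both coefficients are feasible, else the better of the two
# single-column fits with the coefficient clamped at zero.
.nnls2 <- function(A, y) {
  AtA <- crossprod(A)
  Aty <- crossprod(A, y)
  x <- tryCatch(drop(solve(AtA, Aty)), error = function(e) c(-1, -1))
  if (all(x >= 0)) return(x)
  cand <- list(c(max(Aty[1] / AtA[1, 1], 0), 0),
               c(0, max(Aty[2] / AtA[2, 2], 0)))
  rss <- vapply(cand, function(z) sum((y - A %*% z)^2), 0)
  cand[[which.min(rss)]]
}

# Apex intensity near m/z `s` in a profile spectrum: the local maximum within
# +/- tol, refined by a parabola on log intensity (exact for a Gaussian peak
# sampled off its apex).
.apex_intensity <- function(spectrum, s, tol) {
  sel <- which(abs(spectrum$mz - s) <= tol)
  if (!length(sel)) return(0)
  i <- sel[which.max(spectrum$intensity[sel])]
  y0 <- spectrum$intensity[i]
  if (y0 <= 0 || i == 1L || i == length(spectrum$mz)) return(max(y0, 0))
  yl <- spectrum$intensity[i - 1L]; yr <- spectrum$intensity[i + 1L]
  if (yl <= 0 || yr <= 0) return(y0)
  la <- log(yl); lb <- log(y0); lc <- log(yr)
  denom <- la - 2 * lb + lc
  if (denom >= 0) return(y0)  # not concave: keep the sampled maximum
  # vertex offset in grid steps; beyond one step the "apex" belongs to a
  # neighbouring peak outside this slot, so keep the sampled value
  offset <- (la - lc) / (2 * denom)
  if (abs(offset) > 1) return(y0)
  exp(lb - (la - lc)^2 / (8 * denom))
}

#' Estimate the deamidation alpha-value from an isotope envelope
#'
#' Solves, by non-negative least squares, `observed ~ a * T + b * T+`, where
#' `T` is the theoretical isotope distribution of the undeamidated peptide
#' and `T+` the same distribution shifted by the deamidation increment (which
#' lands on the next isotopologue slot at MALDI-TOF resolution). Returns
#' `alpha = a / (a + b)` clipped to \[0, 1\] and the L2-normalized fit
#' residual. Scale-invariant in the envelope intensities.
#'
#' @param envelope A `peak_list`, `maldi_spectrum`, or numeric vector of slot
#'   intensities starting at the monoisotopic slot.
#' @param peptide The undeamidated marker [peptide()].
#' @param n_isotopes Isotopologues of the theoretical distribution (>= 5).
#' @param slot_tol Half-width (Da) used to read slot intensities.
#' @return List with `alpha` and `residual`.
#' @export
estimate_alpha <- function(envelope, peptide, n_isotopes = 6L, slot_tol = 0.3) {
  if (n_isotopes < 5L) stop("n_isotopes must be >= 5")
  dist <- isotope_distribution(peptide, n_isotopes)
  tt <- dist$relative_intensities
  n_slots <- n_isotopes + 1L
  slots <- dist$base_mz + (seq_len(n_slots) - 1L) * dist$spacing
  y <- if (is.numeric(envelope)) {
    c(envelope, numeric(max(0, n_slots - length(envelope))))[seq_len(n_slots)]
  } else if (inherits(envelope, "maldi_spectrum")) {
    vapply(slots, function(s) .apex_intensity(envelope, s, slot_tol), 0)
  } else if (inherits(envelope, "peak_list") || is.data.frame(envelope)) {
    vapply(slots, function(s) {
      d <- abs(envelope$mz - s)
      if (length(d) && min(d) <= slot_tol) envelope$intensity[which.min(d)] else 0
    }, 0)
  } else stop("unsupported envelope type")
  if (all(y == 0)) stop("all-zero envelope: alpha not determinable")
  A <- cbind(undeamidated = c(tt, 0), deamidated = c(0, tt))
  coefs <- .nnls2(A, y)
  if (sum(coefs) <= 0) stop("envelope inconsistent with both components")
  alpha <- min(max(coefs[1] / sum(coefs), 0), 1)
  list(alpha = alpha,
       residual = sqrt(sum((y - A %*% coefs)^2)) / sqrt(sum(y^2)))
}

#' Combine replicate alpha estimates by weighted average
#'
#' Replicate weights default to summed envelope intensity so that weak, noisy
#' spots count less. Failed replicates (`NA` alpha) are dropped; if every
#' replicate failed the result is not determinable (`n.d.`), mirroring poor
#' marker signal in the fingerprint spectrum.
#'
#' @param estimates Data frame (or list of lists) with elements `alpha` and
#'   `weight`; weights must be >= 0 and not all zero among usable replicates.
#' @return An `alpha_estimate`: list with `alpha` (NA when not determinable),
#'   `nd` flag, and the per-replicate table.
#' @export
weighted_alpha <- function(estimates) {
  if (is.data.frame(estimates)) {
    tab <- estimates
  } else {
    tab <- data.frame(
      alpha = vapply(estimates, function(e) as.numeric(e$alpha)[1], 0),
      weight = vapply(estimates, function(e)
        if (is.null(e$weight)) 1 else as.numeric(e$weight)[1], 0))
  }
  if (is.null(tab$weight)) tab$weight <- 1
  if (!nrow(tab)) stop("no replicate estimates supplied")
  if (any(tab$weight < 0, na.rm = TRUE)) stop("weights must be >= 0")
  usable <- !is.na(tab$alpha) & !is.na(tab$weight)
  if (!any(usable) || sum(tab$weight[usable]) <= 0) {
    return(structure(list(alpha = NA_real_, nd = TRUE, per_replicate = tab),
                     class = "alpha_estimate"))
  }
  a <- sum(tab$alpha[usable] * tab$weight[usable]) / sum(tab$weight[usable])
  structure(list(alpha = min(max(a, 0), 1), nd = FALSE, per_replicate = tab),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  if (x$nd) cat("<alpha_estimate> n.d. (no usable replicate)\n")
  else cat(sprintf("<alpha_estimate> alpha = %.3f (%d replicates)\n",
                   x$alpha, nrow(x$per_replicate)))
  invisible(x)
}

#' Sample-level alpha-value from replicate spectra
#'
#' Convenience wrapper: estimates alpha on each replicate spectrum and
#' combines them with intensity weights.
#'
#' @param replicates List of `maldi_spectrum` objects.
#' @param peptide The undeamidated marker [peptide()].
#' @param ... Passed to [estimate_alpha()].
#' @return An `alpha_estimate`.
#' @export
sample_alpha <- function(replicates, peptide, ...) {
  per <- lapply(replicates, function(sp) {
    est <- tryCatch(estimate_alpha(sp, peptide, ...),
                    error = function(e) list(alpha = NA_real_, residual = NA_real_))
    list(alpha = est$alpha, weight = sum(sp$intensity))
  })
  weighted_alpha(per)
}
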