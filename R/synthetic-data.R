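# Synthetic-data generators with known ground truth. They emulate the
# statistical structure the analysis assumes -- FTIR band structure of bone,
# MALDI isotope envelopes with a controllable deamidated fraction, two-class
# (endogenous/contaminant) PSM deamidation tables, and amino-acid alignments
# evolved on a known tree -- so that every estimator can be validated by
# round-trip against the generating truth.

# Evaluate code under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Describe a synthetic fixture scenario
#'
#' Bundles the ground-truth parameters of one simulated study condition:
#' preservation class, FTIR band heights, the true ZooMS alpha-value, the two
#' deamidation-class means of the bone proteome, and the true phylogeny.
#'
#' @param name Text label.
#' @param preservation_class `"well_preserved"` or `"degraded"`.
#' @param ftir_band_heights Named absorbance vector (see [gen_ftir_spectrum()]).
#' @param alpha_true True undeamidated fraction of the ZooMS marker, in
#'   \[0, 1\].
#' @param endo_mean,contam_mean Mean deamidation fractions of the endogenous
#'   and contaminant protein classes, in \[0, 1\].
#' @param n_proteins_per_class Number of proteins drawn per class.
#' @param tree_true An `ape::phylo` with branch lengths, or `NULL`.
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#' @return An object of class `fixture_scenario`.
#' @export
fixture_scenario <- function(name = "demo",
                             preservation_class = c("well_preserved", "degraded"),
                             ftir_band_heights = NULL,
                             alpha_true = 0.75,
                             endo_mean = 0.8,
                             contam_mean = 0.06,
                             n_proteins_per_class = 10L,
                             tree_true = NULL,
                             seed = 1L) {
  preservation_class <- match.arg(preservation_class)
  for (v in c(alpha_true, endo_mean, contam_mean))
    if (v < 0 || v > 1) stop("alpha_true, endo_mean, contam_mean must be in [0, 1]")
  if (n_proteins_per_class < 1L) stop("n_proteins_per_class must be >= 1")
  if (is.null(ftir_band_heights)) {
    ftir_band_heights <- if (preservation_class == "well_preserved")
      c(nu4a = 0.20, nu4b = 0.20, valley = 0.11, phosphate = 1.0,
        carbonate = 0.08, amide = 0.14, oh = 0.25)
    else
      c(nu4a = 0.25, nu4b = 0.24, valley = 0.09, phosphate = 1.0,
        carbonate = 0.10, amide = 0.03, oh = 0.10)
  }
  structure(list(name = name, preservation_class = preservation_class,
                 ftir_band_heights = ftir_band_heights,
                 alpha_true = alpha_true, endo_mean = endo_mean,
                 contam_mean = contam_mean,
                 n_proteins_per_class = as.integer(n_proteins_per_class),
                 tree_true = tree_true, seed = as.integer(seed)),
            class = "fixture_scenario")
}

#' Synthesize a bone ATR-FTIR spectrum
#'
#' Gaussian bands on a linear baseline over a 525-4000 cm^-1 grid at 4 cm^-1
#' spacing: the phosphate nu4 doublet (~605 and ~565 cm^-1) over a compact
#' raised-cosine fill that sets the valley floor at ~590 cm^-1, phosphate nu3
#' (~1010), carbonate (~1420), amide I (~1640) and the broad O-H/amide A
#' region (~3350). The doublet amplitudes are solved from a small linear
#' system so that the baseline-corrected heights at 605, 565 and 590 cm^-1
#' equal the requested `nu4a`, `nu4b` and `valley` values exactly in the
#' noiseless case.
#'
#' @param band_heights Named non-negative absorbances: `nu4a`, `nu4b`,
#'   `valley`, `phosphate`, `carbonate`, `amide`, `oh` (missing entries
#'   default to 0).
#' @param noise_sd Gaussian noise standard deviation (absorbance units, >= 0).
#' @param seed Integer seed.
#' @param baseline Length-2 numeric: intercept and slope (per cm^-1) of the
#'   linear baseline.
#' @return An `ir_spectrum`.
#' @export
gen_ftir_spectrum <- function(band_heights, noise_sd = 0, seed = 1L,
                              baseline = c(0.02, 5e-6)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  h <- c(nu4a = 0, nu4b = 0, valley = 0, phosphate = 0, carbonate = 0,
         amide = 0, oh = 0)
  h[names(band_heights)] <- band_heights
  if (any(h < 0)) stop("band heights must be >= 0")
  x <- seq(525, 4000, by = 4)
  gauss <- function(c0, sd) exp(-0.5 * ((x - c0) / sd)^2)
  # compact raised-cosine valley fill, zero outside 545-625 cm^-1
  rcos <- ifelse(abs(x - 585) < 40,
                 0.5 * (1 + cos(2 * pi * (x - 585) / 80)), 0)
  # solve doublet/fill amplitudes so the summed curve hits the requested
  # heights exactly at 605, 565 and 590 cm^-1
  g605_at <- function(p) exp(-0.5 * ((p - 605) / 5)^2)
  g565_at <- function(p) exp(-0.5 * ((p - 565) / 5)^2)
  rcos_at <- function(p) ifelse(abs(p - 585) < 40,
                                0.5 * (1 + cos(2 * pi * (p - 585) / 80)), 0)
  pts <- c(605, 565, 590)
  M <- cbind(g605_at(pts), g565_at(pts), rcos_at(pts))
  amp <- if (all(h[c("nu4a", "nu4b", "valley")] == 0)) c(0, 0, 0)
         else solve(M, h[c("nu4a", "nu4b", "valley")])
  y <- amp[1] * gauss(605, 5) + amp[2] * gauss(565, 5) + amp[3] * rcos +
    h[["phosphate"]] * gauss(1010, 20) +
    h[["carbonate"]] * gauss(1420, 20) +
    h[["amide"]] * gauss(1640, 15) +
    h[["oh"]] * gauss(3350, 150) +
    baseline[1] + baseline[2] * (x - 525)
  if (noise_sd > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  ir_spectrum(x, y)
}

#' Simulate replicate MALDI spectra of a deamidation mixture
#'
#' The observed isotope envelope of a partially deamidated peptide is modelled
#' as `alpha * T + (1 - alpha) * T+`, where `T` is the theoretical isotope
#' distribution of the undeamidated peptide and `T+` the same distribution
#' shifted by the deamidation increment. Because that increment (+0.9840 Da)
#' differs from the isotopologue spacing (1.00336 Da) by far less than
#' MALDI-TOF peak widths, the shifted distribution is collapsed onto the
#' undeamidated isotopologue slot grid, making the noiseless mixture exact on
#' the slots. Peaks are rendered as Gaussian profiles with multiplicative
#' noise per replicate.
#'
#' @param peptide A [peptide()] (e.g. the collagen marker at m/z 1105).
#' @param alpha_true True undeamidated fraction in \[0, 1\].
#' @param n_replicates Number of replicate spectra (>= 1; instrument practice
#'   is triplicate spotting).
#' @param resolution Peak full width at half maximum, in ppm of m/z.
#' @param noise_sd Relative (multiplicative) intensity noise per grid point.
#' @param seed Integer seed.
#' @param n_isotopes Isotopologues of the theoretical distribution (>= 2).
#' @param scale Intensity of a unit-weight peak (arbitrary counts).
#' @param grid_step m/z grid spacing (Da).
#' @return List of `maldi_spectrum` objects, with the slot m/z positions and
#'   noiseless slot weights attached as attributes `slots` and `weights`.
#' @export
gen_maldi_replicates <- function(peptide, alpha_true, n_replicates = 3L,
                                 resolution = 100, noise_sd = 0, seed = 1L,
                                 n_isotopes = 6L, scale = 1000,
                                 grid_step = 0.01) {
  if (alpha_true < 0 || alpha_true > 1) stop("alpha_true must be in [0, 1]")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  dist <- isotope_distribution(peptide, n_isotopes)
  tt <- dist$relative_intensities
  # slot j carries alpha*T[j] + (1-alpha)*T[j-1]
  w <- alpha_true * c(tt, 0) + (1 - alpha_true) * c(0, tt)
  slots <- dist$base_mz + (seq_along(w) - 1L) * dist$spacing
  mz <- seq(dist$base_mz - 3, dist$base_mz + n_isotopes + 5, by = grid_step)
  sigma <- resolution * 1e-6 * dist$base_mz / (2 * sqrt(2 * log(2)))
  shape <- rowSums(vapply(seq_along(w), function(j)
    w[j] * exp(-0.5 * ((mz - slots[j]) / sigma)^2), numeric(length(mz))))
  base <- scale * shape
  out <- .with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    y <- if (noise_sd > 0)
      pmax(base * (1 + stats::rnorm(length(base), 0, noise_sd)), 0)
    else base
    maldi_spectrum(mz, y)
  }))
  attr(out, "slots") <- slots
  attr(out, "weights") <- w
  out
}

#' Simulate a two-class PSM deamidation table
#'
#' Draws per-protein true deamidation fractions from two Beta classes
#' (endogenous, elevated; contaminant, low), then emits one pair of
#' peptide-spectrum-match rows (deamidated / undeamidated summed intensity)
#' per covered Q/N site, consistent with the protein's true fraction. A few
#' proteins per class receive only two covered sites to exercise the
#' clustering eligibility filter.
#'
#' @param scenario A [fixture_scenario()].
#' @param sites_range Range of covered Q/N sites per ordinary protein.
#' @param n_low_site_proteins Extra proteins per class with exactly 2 sites.
#' @param class_concentration Beta concentration (a+b) of the class
#'   distributions; larger = tighter around the class mean.
#' @param site_concentration Beta concentration of per-site observed fractions
#'   around the protein's true fraction.
#' @return Data frame with columns `protein_id`, `peptide`, `protein_start`,
#'   `site_pos`, `residue`, `deamidated`, `ion_intensity`, `has_b`, `has_y`,
#'   `score`; ground truth in `attr(, "truth")`.
#' @export
gen_psm_table <- function(scenario, sites_range = c(4L, 12L),
                          n_low_site_proteins = 1L,
                          class_concentration = 12,
                          site_concentration = 60) {
  stopifnot(inherits(scenario, "fixture_scenario"))
  .with_seed(scenario$seed, {
    specs <- list()
    add <- function(class, mean, n, n_sites_fixed = NULL) {
      for (i in seq_len(n)) {
        p <- stats::rbeta(1, mean * class_concentration,
                          (1 - mean) * class_concentration)
        p <- min(max(p, 1e-4), 1 - 1e-4)
        ns <- if (is.null(n_sites_fixed))
          sample(seq(sites_range[1], sites_range[2]), 1)
        else n_sites_fixed
        specs[[length(specs) + 1L]] <<- list(class = class, p = p, ns = ns)
      }
    }
    add("endogenous", scenario$endo_mean, scenario$n_proteins_per_class)
    add("contaminant", scenario$contam_mean, scenario$n_proteins_per_class)
    add("endogenous", scenario$endo_mean, n_low_site_proteins, 2L)
    add("contaminant", scenario$contam_mean, n_low_site_proteins, 2L)
    rows <- list(); truth <- list()
    aa_pool <- c("G", "A", "P", "S", "V", "T", "E", "D", "K", "R", "L", "F")
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      pid <- sprintf("%s_%02d", toupper(substr(sp$class, 1, 4)), i)
      truth[[i]] <- data.frame(protein_id = pid, class = sp$class,
                               p_true = sp$p, n_sites = sp$ns)
      pos <- sort(sample(5:295, sp$ns))
      for (k in seq_len(sp$ns)) {
        res <- sample(c("N", "Q"), 1)
        frac <- stats::rbeta(1, sp$p * site_concentration,
                             (1 - sp$p) * site_concentration)
        itot <- stats::rlnorm(1, log(500), 0.6)
        flank <- paste(sample(aa_pool, 8, replace = TRUE), collapse = "")
        pepseq <- paste0(substr(flank, 1, 4), res, substr(flank, 5, 8))
        for (deam in c(TRUE, FALSE)) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pid, peptide = pepseq,
            protein_start = pos[k] - 4L, site_pos = pos[k], residue = res,
            deamidated = deam,
            ion_intensity = itot * if (deam) frac else 1 - frac,
            has_b = TRUE, has_y = TRUE,
            score = stats::runif(1, 20, 100))
        }
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}

#' Simulate PSM sequence evidence over a reference protein
#'
#' Generates tiling peptide-spectrum matches that read out a taxon's true
#' sequence against a reference chain, with controllable PSM depth and b/y
#' fragment support, and optionally planted amino-acid substitutions with
#' their own depth and support. Used to exercise consensus calling and the
#' substitution-authentication rules.
#'
#' @param reference Reference mature-chain sequence (string).
#' @param true_sequence The taxon's actual sequence (defaults to the
#'   reference); positions where it differs are carried by all covering PSMs.
#' @param depth PSMs covering each position (tiles do not overlap, so this is
#'   exactly the per-site PSM depth).
#' @param peptide_length Tiling peptide length.
#' @param has_b,has_y Fragment-ion support flags applied to the PSMs.
#' @param uncovered Integer positions left without any PSM.
#' @param seed Integer seed (intensities).
#' @return PSM data frame with columns `protein_id`, `peptide`,
#'   `protein_start`, `ion_intensity`, `has_b`, `has_y`, `score`.
#' @export
gen_consensus_psms <- function(reference, true_sequence = reference,
                               depth = 3L, peptide_length = 9L,
                               has_b = TRUE, has_y = TRUE,
                               uncovered = integer(), protein_id = "PROT",
                               seed = 1L) {
  n <- nchar(reference)
  stopifnot(nchar(true_sequence) == n)
  .with_seed(seed, {
    rows <- list()
    starts <- seq(1L, n, by = peptide_length)
    for (s in starts) {
      span <- s:min(s + peptide_length - 1L, n)
      if (any(span %in% uncovered)) next
      pepseq <- substr(true_sequence, span[1], span[length(span)])
      for (d in seq_len(depth)) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = protein_id, peptide = pepseq,
          protein_start = s, ion_intensity = stats::rlnorm(1, log(300), 0.5),
          has_b = has_b, has_y = has_y, score = stats::runif(1, 30, 100))
      }
    }
    do.call(rbind, rows)
  })
}

#' Evolve an amino-acid alignment on a known tree
#'
#' I.i.d. site evolution under an equal-rates, equal-frequency model over the
#' 20 amino-acid alphabet (the 20-state analogue of the Jukes-Cantor model):
#' along a branch of length `t` the probability of remaining in the current
#' state is `1/20 + 19/20 * exp(-20/19 * rate * t)`, with the remainder spread
#' evenly over the other 19 states.
#'
#' @param tree_true An `ape::phylo` with >= 4 leaves and branch lengths.
#' @param n_sites Number of sites (>= 1).
#' @param subst_rate Substitution rate multiplier (>= 0).
#' @param seed Integer seed.
#' @return Character matrix (taxa x sites) with taxon rownames.
#' @export
simulate_alignment <- function(tree_true, n_sites, subst_rate, seed = 1L) {
  stopifnot(inherits(tree_true, "phylo"))
  if (length(tree_true$tip.label) < 4L) stop("tree must have >= 4 leaves")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (subst_rate < 0) stop("subst_rate must be >= 0")
  if (is.null(tree_true$edge.length)) stop("tree must have branch lengths")
  aa <- rownames(.RESIDUE_COMPOSITION)
  n_tip <- length(tree_true$tip.label)
  root <- n_tip + 1L
  .with_seed(seed, {
    states <- vector("list", max(tree_true$edge))
    states[[root]] <- sample.int(20L, n_sites, replace = TRUE)
    # cladewise edge order visits parents before children
    ord <- ape::reorder.phylo(tree_true, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      t_e <- ord$edge.length[e]
      p_stay <- 1 / 20 + 19 / 20 * exp(-20 / 19 * subst_rate * t_e)
      s <- states[[par]]
      change <- stats::runif(n_sites) > p_stay
      if (any(change)) {
        shift <- sample.int(19L, sum(change), replace = TRUE)
        s[change] <- ((s[change] - 1L + shift) %% 20L) + 1L
      }
      states[[child]] <- s
    }
    mat <- t(vapply(seq_len(n_tip), function(i) aa[states[[i]]],
                    character(n_sites)))
    rownames(mat) <- tree_true$tip.label
    mat
  })
}

#' Count parsimony-informative sites
#'
#' A site is parsimony-informative when at least two states each occur in at
#' least two taxa; missing symbols (`X`, `-`, `?`) are ignored.
#'
#' @param matrix Character matrix, taxa x sites.
#' @return Integer count.
#' @export
count_informative_sites <- function(matrix) {
  sum(apply(matrix, 2, function(col) {
    col <- col[!col %in% c("X", "-", "?")]
    tab <- table(col)
    sum(tab >= 2) >= 2
  }))
}
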