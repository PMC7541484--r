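# Endogeneity assessment of bone-proteome proteins from Q/N deamidation.
#
# Ancient (endogenous) proteins accumulate deamidation over time while modern
# contaminants (keratins, laboratory enzymes) do not, so per-protein
# deamidation frequencies separate into a low and a high component. The
# frequency is intensity-pooled across a protein's quantifiable Q/N sites,
# and a two-component univariate Gaussian mixture fitted by EM assigns each
# protein to the endogenous (higher-mean) or contaminant class.

#' Per-protein deamidation frequency from PSM intensities
#'
#' Pools summed ion intensities over the protein's Q/N site-observations:
#' frequency = sum(deamidated intensity) / sum(total intensity) across sites
#' whose total intensity is at least `min_intensity`. `nq_count` is the
#' number of such quantifiable sites.
#'
#' @param psms PSM data frame with columns `protein_id`, `site_pos`,
#'   `residue`, `deamidated`, `ion_intensity` (one row per
#'   deamidated/undeamidated site observation; see [gen_psm_table()] and
#'   [read_psm_table()]).
#' @param protein_id Protein to quantify.
#' @param min_intensity Minimum summed site intensity to count a site as
#'   quantifiable (default 0: every observed site counts).
#' @return A `protein_deamidation`: list with `protein_id`, `nq_count`,
#'   `deamidation_frequency`.
#' @export
protein_deamidation_frequency <- function(psms, protein_id, min_intensity = 0) {
  rows <- psms[psms$protein_id == protein_id & !is.na(psms$site_pos), ,
               drop = FALSE]
  if (!nrow(rows))
    stop(sprintf("no Q/N site observation for protein %s", protein_id))
  site_tot <- tapply(rows$ion_intensity, rows$site_pos, sum)
  keep <- names(site_tot)[site_tot >= min_intensity & site_tot > 0]
  if (!length(keep))
    stop(sprintf("no quantifiable Q/N site observation for protein %s",
                 protein_id))
  rows <- rows[rows$site_pos %in% as.numeric(keep), , drop = FALSE]
  freq <- sum(rows$ion_intensity[rows$deamidated]) / sum(rows$ion_intensity)
  structure(list(protein_id = protein_id, nq_count = length(keep),
                 deamidation_frequency = freq),
            class = "protein_deamidation")
}

#' @export
print.protein_deamidation <- function(x, ...) {
  cat(sprintf("<protein_deamidation> %s: %.1f%% over %d Q/N sites\n",
              x$protein_id, 100 * x$deamidation_frequency, x$nq_count))
  invisible(x)
}

#' Eligibility of a protein for cluster analysis
#'
#' A protein enters the mixture clustering only when more than two Q/N
#' positions are covered by quantifiable PSM evidence.
#'
#' @param protein A `protein_deamidation` (or a list with `nq_count`).
#' @return Logical.
#' @export
eligible_for_clustering <- function(protein) {
  isTRUE(protein$nq_count > 2)
}

#' Deamidation summary table over all proteins
#'
#' @param psms PSM data frame (see [protein_deamidation_frequency()]).
#' @param min_intensity Passed through.
#' @return Data frame with columns `protein_id`, `n_psm`, `n_peptides`,
#'   `nq_count`, `deamidation_frequency`, `eligible`.
#' @export
deamidation_table <- function(psms, min_intensity = 0) {
  ids <- unique(psms$protein_id)
  rows <- lapply(ids, function(id) {
    sub <- psms[psms$protein_id == id, , drop = FALSE]
    pd <- tryCatch(protein_deamidation_frequency(psms, id, min_intensity),
                   error = function(e) NULL)
    data.frame(protein_id = id,
               n_psm = nrow(sub),
               n_peptides = length(unique(sub$peptide)),
               nq_count = if (is.null(pd)) 0L else pd$nq_count,
               deamidation_frequency = if (is.null(pd)) NA_real_
                                       else pd$deamidation_frequency,
               eligible = if (is.null(pd)) FALSE else eligible_for_clustering(pd))
  })
  do.call(rbind, rows)
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Expectation-maximization with multiple random restarts (initial means are
#' random pairs of distinct data values), a variance floor for numerical
#' stability, and a log-likelihood convergence tolerance. Components are
#' returned ordered by increasing mean. Deterministic given `seed`.
#'
#' @param values Numeric vector of deamidation fractions (>= 4 values, not
#'   all identical).
#' @param n_restarts Number of EM restarts (default 50).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations per restart.
#' @param var_floor Lower bound on component variances.
#' @param seed Integer seed controlling the restarts.
#' @return A `mixture_fit`: list with `means`, `variances`, `weights`,
#'   `posteriors` (matrix, column 2 = higher-mean component), `loglik`,
#'   `loglik_trace` of the best restart, and the input `values`.
#' @export
fit_two_component_mixture <- function(values, n_restarts = 50L, tol = 1e-8,
                                      max_iter = 1000L, var_floor = 1e-7,
                                      seed = 1L) {
  values <- as.numeric(values)
  if (length(values) < 4L) stop("need at least 4 values to fit the mixture")
  if (stats::sd(values) == 0)
    stop("degenerate fit: all values identical")
  n <- length(values)
  em_once <- function(mu) {
    sig2 <- rep(max(stats::var(values) / 2, var_floor), 2)
    w <- c(0.5, 0.5)
    ll_old <- -Inf; trace <- numeric()
    for (it in seq_len(max_iter)) {
      dens <- vapply(1:2, function(k)
        w[k] * stats::dnorm(values, mu[k], sqrt(sig2[k])), numeric(n))
      rowsum_d <- pmax(rowSums(dens), .Machine$double.xmin)
      ll <- sum(log(rowsum_d))
      trace <- c(trace, ll)
      post <- dens / rowsum_d
      nk <- pmax(colSums(post), .Machine$double.eps)
      mu <- colSums(post * values) / nk
      sig2 <- pmax(colSums(post * (outer(values, mu, "-"))^2) / nk, var_floor)
      w <- nk / n
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(mu = mu, sig2 = sig2, w = w, post = post, ll = ll, trace = trace)
  }
  fits <- .with_seed(seed, {
    inits <- c(list(stats::quantile(values, c(0.25, 0.75), names = FALSE)),
               lapply(seq_len(max(0L, n_restarts - 1L)), function(i) {
                 v <- sample(values, 2L)
                 while (v[1] == v[2]) v <- sample(values, 2L)
                 v
               }))
    lapply(inits, em_once)
  })
  best <- fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]
  ord <- order(best$mu)
  structure(list(means = best$mu[ord], variances = best$sig2[ord],
                 weights = best$w[ord],
                 posteriors = best$post[, ord, drop = FALSE],
                 loglik = best$ll, loglik_trace = best$trace,
                 values = values),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> means %.3f / %.3f, weights %.2f / %.2f, loglik %.2f\n",
    x$means[1], x$means[2], x$weights[1], x$weights[2], x$loglik))
  invisible(x)
}

#' Classify proteins as endogenous or contaminant
#'
#' The mixture component with the larger mean is labelled endogenous; each
#' protein goes to its maximum-posterior component. An exact posterior tie
#' (0.5) is broken conservatively to contaminant, with a warning.
#'
#' @param mixture A `mixture_fit` from [fit_two_component_mixture()].
#' @param protein_ids Optional names for the fitted values.
#' @return An `endogeneity_result`: list with `assignments` (factor
#'   endogenous/contaminant), `component_means` (named: contaminant,
#'   endogenous), `posterior_endogenous`.
#' @export
classify_endogeneity <- function(mixture, protein_ids = NULL) {
  stopifnot(inherits(mixture, "mixture_fit"))
  p_endo <- mixture$posteriors[, 2]
  if (any(p_endo == 0.5))
    warning("posterior tie at 0.5 broken to contaminant")
  cls <- ifelse(p_endo > 0.5, "endogenous", "contaminant")
  if (!is.null(protein_ids)) names(cls) <- names(p_endo) <- protein_ids
  structure(list(
    assignments = factor(cls, levels = c("contaminant", "endogenous")),
    component_means = c(contaminant = mixture$means[1],
                        endogenous = mixture$means[2]),
    posterior_endogenous = p_endo),
    class = "endogeneity_result")
}

#' @export
print.endogeneity_result <- function(x, ...) {
  tab <- table(x$assignments)
  cat(sprintf(
    "<endogeneity_result> %d endogenous (mean %.2f), %d contaminant (mean %.2f)\n",
    tab[["endogenous"]], x$component_means[["endogenous"]],
    tab[["contaminant"]], x$component_means[["contaminant"]]))
  invisible(x)
}

#' End-to-end endogeneity analysis of a PSM table
#'
#' Computes per-protein deamidation frequencies, applies the eligibility
#' filter (more than two quantifiable Q/N positions), fits the two-component
#' mixture and classifies the eligible proteins.
#'
#' @param psms PSM data frame.
#' @param min_intensity Passed to [protein_deamidation_frequency()].
#' @param seed Seed for the EM restarts.
#' @return List with `table` (the [deamidation_table()] plus a `class`
#'   column, `NA` for ineligible proteins), `mixture`, and `result`.
#' @export
endogeneity_analysis <- function(psms, min_intensity = 0, seed = 1L) {
  tab <- deamidation_table(psms, min_intensity)
  el <- tab[tab$eligible, , drop = FALSE]
  if (nrow(el) < 4L)
    stop("fewer than 4 proteins eligible for clustering")
  fit <- fit_two_component_mixture(el$deamidation_frequency, seed = seed)
  res <- classify_endogeneity(fit, protein_ids = el$protein_id)
  tab$class <- NA_character_
  tab$class[match(el$protein_id, tab$protein_id)] <-
    as.character(res$assignments)
  list(table = tab, mixture = fit, result = res)
}

#' Read / write a PSM table as TSV
#'
#' Tab-separated with header; columns as produced by [gen_psm_table()]
#' (deamidation rows) and/or [gen_consensus_psms()] (sequence-evidence rows);
#' missing columns are filled with `NA`.
#'
#' @param path File path.
#' @export
read_psm_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param psms PSM data frame.
#' @rdname read_psm_table
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
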