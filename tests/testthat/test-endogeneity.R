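make_psms <- function(rows) do.call(rbind, lapply(rows, as.data.frame))

test_that("deamidation frequency pools intensities across sites", {
  psms <- make_psms(list(
    list(protein_id = "P1", peptide = "AQK", protein_start = 1, site_pos = 2,
         residue = "Q", deamidated = TRUE, ion_intensity = 300,
         has_b = TRUE, has_y = TRUE, score = 50),
    list(protein_id = "P1", peptide = "ANK", protein_start = 10, site_pos = 11,
         residue = "N", deamidated = FALSE, ion_intensity = 700,
         has_b = TRUE, has_y = TRUE, score = 50)
  ))
  pd <- protein_deamidation_frequency(psms, "P1")
  expect_equal(pd$deamidation_frequency, 0.30)
  expect_equal(pd$nq_count, 2L)
  # all-deamidated protein reaches 100%
  psms$deamidated <- TRUE
  expect_equal(protein_deamidation_frequency(psms, "P1")$deamidation_frequency,
               1.0)
  # intensity rescaling does not change the frequency
  psms2 <- psms; psms2$deamidated <- c(TRUE, FALSE)
  psms3 <- psms2; psms3$ion_intensity <- psms3$ion_intensity * 55
  expect_equal(protein_deamidation_frequency(psms3, "P1")$deamidation_frequency,
               protein_deamidation_frequency(psms2, "P1")$deamidation_frequency)
  expect_error(protein_deamidation_frequency(psms, "NOPE"), "no Q/N site")
  zero <- psms2; zero$ion_intensity <- 0
  expect_error(protein_deamidation_frequency(zero, "P1"), "no quantifiable")
})

test_that("generator round-trip recovers the true fraction at high depth", {
  sc <- fixture_scenario(endo_mean = 0.72, n_proteins_per_class = 3L,
                         seed = 42L)
  psms <- gen_psm_table(sc, sites_range = c(30L, 40L),
                        site_concentration = 400)
  truth <- attr(psms, "truth")
  endo_ids <- truth$protein_id[truth$class == "endogenous" & truth$n_sites > 2]
  for (id in endo_ids) {
    pd <- protein_deamidation_frequency(psms, id)
    expect_equal(pd$deamidation_frequency,
                 truth$p_true[truth$protein_id == id], tolerance = 0.02)
  }
})

test_that("clustering eligibility requires more than two covered positions", {
  expect_true(eligible_for_clustering(list(nq_count = 3)))
  expect_false(eligible_for_clustering(list(nq_count = 2)))
  expect_false(eligible_for_clustering(list(nq_count = 0)))
  # generated low-site proteins are excluded by the rule
  sc <- fixture_scenario(seed = 5L)
  tab <- deamidation_table(gen_psm_table(sc))
  expect_true(any(tab$nq_count == 2 & !tab$eligible))
})

test_that("EM mixture separates well-separated values and is monotone", {
  vals <- c(0.05, 0.06, 0.07, 0.90, 0.92, 0.95)
  fit <- fit_two_component_mixture(vals, seed = 1)
  expect_equal(fit$means, c(0.06, 0.923333), tolerance = 0.01)
  expect_true(all(fit$posteriors[vals < 0.5, 1] > 0.999))
  expect_true(all(fit$posteriors[vals > 0.5, 2] > 0.999))
  # log-likelihood never decreases across EM iterations
  expect_true(all(diff(fit$loglik_trace) > -1e-9))
  expect_error(fit_two_component_mixture(rep(0.5, 6)), "degenerate")
  expect_error(fit_two_component_mixture(c(0.1, 0.9, 0.5)), "at least 4")
})

test_that("EM agrees with the reference mixture implementation", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  set.seed(99)
  vals <- c(rbeta(20, 2, 18), rbeta(20, 16, 4))
  fit <- fit_two_component_mixture(vals, seed = 2)
  mc <- mclust::Mclust(vals, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  ours <- ifelse(fit$posteriors[, 2] > 0.5, 2, 1)
  theirs <- if (mc$parameters$mean[1] < mc$parameters$mean[2])
    mc$classification else 3 - mc$classification
  expect_gte(mean(ours == theirs), 0.95)
})

test_that("classification labels the higher-mean component endogenous", {
  # one digestion-enzyme analogue at 11% among ancient proteins
  vals <- c(0.11, 0.40, 0.55, 0.63, 0.71, 0.80, 0.92, 1.00)
  fit <- fit_two_component_mixture(vals, seed = 3)
  res <- classify_endogeneity(fit, protein_ids = paste0("P", seq_along(vals)))
  expect_equal(as.character(res$assignments[1]), "contaminant")
  expect_true(all(res$assignments[-1] == "endogenous"))
  expect_gt(res$component_means[["endogenous"]],
            res$component_means[["contaminant"]])
  # keratin-like low-deamidation cluster with a high ancient cluster:
  # every low value lands in the contaminant class
  vals2 <- c(0.02, 0.04, 0.06, 0.08, 0.10, 0.12, 0.85, 0.9, 0.95, 1.0)
  res2 <- classify_endogeneity(fit_two_component_mixture(vals2, seed = 3))
  expect_true(all(res2$assignments[vals2 < 0.2] == "contaminant"))
})

test_that("two-class scenarios are recovered near-perfectly across seeds", {
  hits <- sapply(1:20, function(s) {
    sc <- fixture_scenario(endo_mean = 0.8, contam_mean = 0.06,
                           n_proteins_per_class = 10L, seed = s)
    psms <- gen_psm_table(sc)
    res <- endogeneity_analysis(psms, seed = s)
    truth <- attr(psms, "truth")
    tab <- res$table[!is.na(res$table$class), ]
    m <- merge(tab, truth, by = "protein_id")
    mean(m$class.x == m$class.y)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("PSM tables round-trip through TSV", {
  sc <- fixture_scenario(seed = 8L)
  psms <- gen_psm_table(sc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, path)
  rt <- read_psm_table(path)
  expect_equal(nrow(rt), nrow(psms))
  expect_equal(rt$ion_intensity, psms$ion_intensity, tolerance = 1e-9)
  expect_equal(deamidation_table(rt)$deamidation_frequency,
               deamidation_table(psms)$deamidation_frequency,
               tolerance = 1e-9)
})
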