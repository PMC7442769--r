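test_that("mass deviation is signed ppm on the neutral mass", {
  expect_equal(massDeviationPpm(mzFromMass(1000.007, 2), 2, 1000), 7,
               tolerance = 1e-9)
  expect_equal(massDeviationPpm(mzFromMass(1000, 3), 3, 1000), 0)
  expect_equal(massDeviationPpm(mzFromMass(999.993, 2), 2, 1000), -7,
               tolerance = 1e-9)
  expect_error(massDeviationPpm(500, 2, -1), "positive")
  expect_error(massDeviationPpm(500, 0, 1000), "charge")
})

test_that("retention-time windows span all MS/MS detections per drug product", {
  det <- data.frame(drug_product = c("DP1", "DP1", "DP1", "DP2"),
                    peptide = "AAAK", mods = "", z = 2L,
                    rt_min = c(40.2, 40.6, 40.4, 55.0),
                    width = c(0.3, 0.32, NA, 0.28), stringsAsFactors = FALSE)
  win <- buildRtWindows(det)
  w1 <- win[win$drug_product == "DP1", ]
  expect_equal(c(w1$rt_lo, w1$rt_hi), c(40.2, 40.6))
  expect_equal(w1$mean_width, mean(c(0.3, 0.32)))
  w2 <- win[win$drug_product == "DP2", ]
  expect_equal(c(w2$rt_lo, w2$rt_hi), c(55, 55))   # singleton: zero width
  expect_equal(nrow(win), 2L)                       # independent per product
})

fakeFeature <- function(mz, z, rt, width, area = 1e5) {
  data.frame(run_id = "r1", mz = mz, z = z, rt_center_min = rt,
             rt_width_min = width, area = area,
             iso0 = 10, iso1 = 5, iso2 = 2, stringsAsFactors = FALSE)
}

test_that("candidate gating applies RT, width and ppm tolerances", {
  win <- list(rt_lo = 40.2, rt_hi = 40.6, mean_width = 0.30)
  theo_mz <- 600
  cfg <- hcpConfig()
  # 40.9 min is inside [39.7, 41.1]
  got <- findCandidates(fakeFeature(600.001, 2L, 40.9, 0.32), win, theo_mz,
                        2L, cfg)
  expect_equal(nrow(got), 1L)
  # 41.2 min falls outside the widened window
  expect_equal(nrow(findCandidates(fakeFeature(600.001, 2L, 41.2, 0.32),
                                   win, theo_mz, 2L, cfg)), 0L)
  # width change beyond 0.1 min
  expect_equal(nrow(findCandidates(fakeFeature(600.001, 2L, 40.5, 0.45),
                                   win, theo_mz, 2L, cfg)), 0L)
  # wrong charge
  expect_equal(nrow(findCandidates(fakeFeature(600.001, 3L, 40.5, 0.30),
                                   win, theo_mz, 2L, cfg)), 0L)
  # beyond the 7 ppm precursor gate
  expect_equal(nrow(findCandidates(fakeFeature(600.006, 2L, 40.5, 0.30),
                                   win, theo_mz, 2L, cfg)), 0L)
})

test_that("the m/z-closest qualifying candidate is retained", {
  feats <- rbind(fakeFeature(600 * (1 + 3e-6), 2L, 40.4, 0.3),
                 fakeFeature(600 * (1 + 1e-6), 2L, 40.5, 0.3))
  win <- list(rt_lo = 40.2, rt_hi = 40.6, mean_width = 0.30)
  got <- findCandidates(feats, win, 600, 2L, hcpConfig())
  expect_equal(nrow(got), 1L)
  expect_equal(got$ppm_dev_mz, 1, tolerance = 1e-6)
})

test_that("percentile reference uses interpolated empirical percentiles", {
  ref <- percentileReference(rep(c(-2, -1, 0, 1, 2), 20), rep(0.99, 100))
  expect_equal(ref$massdev_lo, -2)
  expect_equal(ref$massdev_hi, 2)
  expect_equal(ref$corr_lo, 0.99)

  # degenerate distributions collapse the band to a point
  ref2 <- percentileReference(rep(3, 30), rep(1, 30))
  expect_equal(c(ref2$massdev_lo, ref2$massdev_hi), c(3, 3))
  expect_equal(ref2$corr_lo, 1)

  expect_error(percentileReference(rnorm(10), runif(10)),
               "fewer than 20 reference")
})

test_that("acceptance records the first failed criterion in order", {
  th <- list(massdev_lo = -2, massdev_hi = 2, corr_lo = 0.95)
  expect_true(acceptInSilico(0, 1.0, 5L, th)$accepted)
  out_dev <- acceptInSilico(3, 1.0, 5L, th)
  expect_false(out_dev$accepted)
  expect_equal(out_dev$rejection_reason, "mass_dev")
  out_corr <- acceptInSilico(0, 0.5, 5L, th)
  expect_equal(out_corr$rejection_reason, "correlation")
  out_low <- acceptInSilico(0, NA, 2L, th)
  expect_equal(out_low$rejection_reason, "low_information")
  # mass deviation is checked before envelope information content
  expect_equal(acceptInSilico(3, NA, 2L, th)$rejection_reason, "mass_dev")
})

test_that("rescue transfers identifications without duplicating MS/MS detections", {
  cfg <- simConfig(seed = 19, n_hcps = 10, n_drug_products = 1,
                   n_fractions_per_dp = 2, protein_length = 140,
                   missingness = 0.4, n_bait = 3)
  simdb <- simulateDatabase(cfg)
  sim <- simulateRuns(simdb$database, cfg)
  kept <- sim$psms[!sim$psms$decoy, ]
  res <- rescuePeptides(kept, sim$features, sim$meta, hcpConfig())
  expect_gt(sum(res$matches$accepted), 0)
  # no in silico match for a (run, peptide ion) already seen by MS/MS
  seen <- paste(kept$run_id, kept$peptide, kept$mods, kept$z)
  got <- with(res$matches, paste(run_id, peptide, mods, z))
  expect_length(intersect(got, seen), 0L)
  # at most one accepted match per (run, peptide ion)
  acc <- res$matches[res$matches$accepted, ]
  expect_equal(anyDuplicated(with(acc, paste(run_id, peptide, mods, z))), 0L)
  # rejection reasons are only the documented ones
  expect_true(all(res$matches$rejection_reason[!res$matches$accepted] %in%
                  c("rt", "mass_dev", "correlation", "low_information")))
})

test_that("per-drug-product percentile scope returns one threshold set per product", {
  cfg <- simConfig(seed = 23, n_hcps = 8, n_drug_products = 2,
                   n_fractions_per_dp = 1, protein_length = 140,
                   missingness = 0.3, n_bait = 0)
  simdb <- simulateDatabase(cfg)
  sim <- simulateRuns(simdb$database, cfg)
  kept <- sim$psms[!sim$psms$decoy, ]
  res <- rescuePeptides(kept, sim$features, sim$meta, hcpConfig(),
                        scope = "drug_product")
  expect_setequal(names(res$thresholds), c("DP1", "DP2"))
  expect_true(all(vapply(res$thresholds, function(t)
    t$massdev_lo < t$massdev_hi, TRUE)))
})
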