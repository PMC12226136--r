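# Generator determinism, null behaviour, parameter recovery, power
# monotonicity, and null calibration of the background z distribution.

test_that("simulation is a pure function of its configuration", {
  cfg <- synthetic_config(seed = 5)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_experiment(synthetic_config(seed = 6))
  expect_false(identical(a$observations, c2$observations))
})

test_that("observations satisfy the peptide-table invariants", {
  sim <- simulate_experiment(synthetic_config(seed = 5))
  expect_silent(validate_observations(
    sim$observations, stats::setNames(list(sim$protein),
                                      sim$protein$id)))
  # every semi peptide traces to exactly one provenance
  expect_equal(nrow(sim$truth$provenance), nrow(sim$observations))
  expect_true(all(sim$truth$provenance$provenance %in%
                    c("fully", "background", "planted")))
  # planted semi evidence carries its source site
  pl <- sim$truth$provenance
  expect_true(all(!is.na(pl$planted_p1[pl$provenance == "planted"])))
  expect_true(all(is.na(pl$planted_p1[pl$provenance != "planted"])))
})

test_that("with nothing planted and no background the caller stays silent", {
  for (s in 1:3) {
    sim <- simulate_experiment(
      synthetic_config(seed = s, n_planted = 0, background_semi_rate = 0))
    res <- call_experiment(sim$observations)
    expect_equal(nrow(res$calls), 0L)
    rep <- recovery_report(res$calls, sim$truth)
    expect_false(rep$precision_defined)
    expect_equal(rep$precision, 1)   # by convention, flagged
  }
})

test_that("the default experiment is recovered with high recall and no false positives", {
  sim <- simulate_experiment(synthetic_config())
  res <- call_experiment(sim$observations, enzyme = "SYN",
                         proteins = stats::setNames(list(sim$protein),
                                                    sim$protein$id))
  rep <- recovery_report(res$calls, sim$truth)
  expect_gte(rep$recall, 0.9)
  expect_equal(rep$precision, 1.0)
  expect_length(rep$false_positives, 0L)
})

test_that("recall grows with cleavage fraction and shrinks with noise", {
  grid <- expand.grid(frac = c(0.3, 0.55, 0.8),
                      noise = c(0.05, 0.1, 0.2))
  rec <- mapply(function(f, nz) {
    sim <- simulate_experiment(
      synthetic_config(cleavage_fraction = f, noise_cv = nz))
    recovery_report(call_experiment(sim$observations)$calls,
                    sim$truth)$recall
  }, grid$frac, grid$noise)
  rec <- matrix(rec, nrow = 3,
                dimnames = list(paste0("f", c(0.3, 0.55, 0.8)),
                                paste0("cv", c(0.05, 0.1, 0.2))))
  # non-decreasing down each column (fraction), non-increasing along each
  # row (noise)
  expect_true(all(apply(rec, 2, function(col) all(diff(col) >= 0))))
  expect_true(all(apply(rec, 1, function(row) all(diff(row) <= 0))))
})

test_that("background semi peptides are z-calibrated like a null sample", {
  cfg <- synthetic_config(seed = 11, protein_length = 2000, n_planted = 0)
  sim <- simulate_experiment(cfg)
  res <- call_experiment(sim$observations)
  bg <- sim$truth$provenance$obs_id[
    sim$truth$provenance$provenance == "background"]
  z <- res$records$z[match(bg, res$records$obs_id)]
  expect_gt(length(z), 300L)
  p_exp <- 2 * stats::pnorm(-2)
  se <- sqrt(p_exp * (1 - p_exp) / length(z))
  expect_lt(abs(mean(abs(z) >= 2) - p_exp), 4 * se)
})

test_that("recovery_report applies the stated conventions", {
  truth <- list(planted = data.frame(p1_pos = c(10L, 20L),
                                     fraction = c(0.5, 0.5)))
  calls <- data.frame(protein_id = "P", p1_pos = c(10L, 20L),
                      enzyme = "E")
  rep <- recovery_report(calls, truth)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  rep <- recovery_report(calls[0, ], truth)
  expect_equal(rep$recall, 0)
  expect_equal(rep$precision, 1)
  expect_false(rep$precision_defined)
  rep <- recovery_report(data.frame(protein_id = "P", p1_pos = 11L,
                                    enzyme = "E"), truth)
  expect_equal(rep$precision, 0)
  expect_equal(rep$false_positives, 11L)
})

test_that("planting on a working-protease site warns of invisibility", {
  set.seed(9)
  p <- random_protein(120)
  site <- theoretical_sites(p, protease_rule("trypsin"))[1]
  cfg <- synthetic_config(
    seed = 9, protein = p,
    planted_sites = data.frame(p1_pos = site, fraction = 0.8))
  expect_warning(simulate_experiment(cfg), "invisible")
})
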