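# z-scoring, abundance fences, site calling, spanning corroboration.

make_pair <- function(ratios_log2, base = 18, wp = "trypsin") {
  # observations whose log2(E/EQ) equals ratios_log2 exactly
  n <- length(ratios_log2)
  do.call(rbind, lapply(seq_len(n), function(i) {
    obs_row(paste0(random_seq(6)), "A", "A", 10 * i, wp = wp,
            E = 2 ^ (base + ratios_log2[i]), EQ = 2 ^ base)
  }))
}

test_that("z-scores standardise log2 ratios over co-quantified peptides", {
  set.seed(1)
  obs <- make_pair(c(0, 0, 0, 0, 10))
  r <- compute_ratios(obs)
  # hand-computed sample statistics: mean 2, sd sqrt(20)
  expect_equal(r$log2_ratio, c(0, 0, 0, 0, 10))
  expect_equal(r$z[5], 8 / sqrt(20), tolerance = 1e-12)
  expect_equal(r$z[1], -2 / sqrt(20), tolerance = 1e-12)

  # a peptide at the population mean scores zero
  obs <- make_pair(c(1, 2, 3))
  expect_equal(compute_ratios(obs)$z[2], 0, tolerance = 1e-12)

  # normalisation invariant: mean 0, sd 1
  set.seed(2)
  obs <- make_pair(rnorm(40, 0, 1.3))
  r <- compute_ratios(obs)
  expect_equal(mean(r$z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(r$z), 1, tolerance = 1e-9)
})

test_that("degenerate and under-sized ratio populations are rejected", {
  expect_error(compute_ratios(make_pair(c(1, 1, 1, 1))), "degenerate")
  expect_error(compute_ratios(make_pair(c(0, 1))), "fewer than 3")
  bad <- make_pair(c(0, 1, 2))
  bad$abundance_E[1] <- 0
  expect_error(compute_ratios(bad), "positive")
})

test_that("group-exclusive peptides are side-channelled, not z-scored", {
  obs <- rbind(make_pair(c(0, 0.5, -0.5, 1)),
               obs_row("AAAAK", "R", "A", 200, E = 2^19, EQ = NA),
               obs_row("CCCCK", "R", "A", 210, E = NA, EQ = 2^19))
  r <- compute_ratios(obs)
  expect_equal(r$exclusive_group[5:6], c("E_only", "EQ_only"))
  expect_true(all(is.na(r$z[5:6])))
  expect_equal(mean(r$z[1:4]), 0, tolerance = 1e-9)
})

test_that("trypsin and GluC digests are z-scored separately", {
  obs <- rbind(make_pair(c(0, 0, 0, 6), wp = "trypsin"),
               make_pair(c(0, 0, 0, -6), wp = "gluc"))
  r <- compute_ratios(obs)
  for (wp in c("trypsin", "gluc")) {
    sel <- r$working_protease == wp
    expect_equal(mean(r$z[sel]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(r$z[sel]), 1, tolerance = 1e-9)
  }
})

test_that("Tukey fences use interpolated quartiles and k * IQR", {
  f <- abundance_fence(c(10, 12, 14, 16, 18))
  expect_equal(f$q1, 12)
  expect_equal(f$q3, 16)
  expect_equal(f$iqr, 4)
  expect_equal(f$lower_fence, 6)
  expect_equal(f$upper_fence, 22)

  f0 <- abundance_fence(rep(7, 6))
  expect_equal(f0$iqr, 0)
  expect_equal(f0$lower_fence, 7)
  expect_equal(f0$upper_fence, 7)

  x <- 0:100
  f <- abundance_fence(x)
  expect_equal(f$q1, oracle_quantile7(x, 0.25))
  expect_equal(f$q3, oracle_quantile7(x, 0.75))
  set.seed(3)
  x <- rnorm(57)
  f <- abundance_fence(x, k = 2)
  expect_equal(f$lower_fence,
               oracle_quantile7(x, 0.25) -
                 2 * (oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25)))
  expect_error(abundance_fence(c(1, 2, 3)), "at least 4")
})

test_that("peptides implying one bond merge into a single call", {
  # the 13 significant ADAMTS1 V2 peptides collapse to 12 unique sites:
  # two peptides support V26-G27
  tab <- load_fixture("Table4", enzyme = "ADAMTS1", row_class = "semi")
  cl <- do.call(rbind, lapply(split(tab, tab$working_protease), function(b)
    classify_peptides(b, protease_rule(b$working_protease[1]))))
  calls <- calls_from_semi(cl, enzyme = "ADAMTS1",
                           proteins = fixture_proteins())
  expect_equal(nrow(calls), 12L)
  v26 <- calls[calls$p1_pos == 26L, ]
  expect_equal(v26$n_semi_peptides, 2L)
  expect_equal(v26$p1_aa, "V")
  expect_equal(v26$p1prime_aa, "G")

  # the 8 significant V1 peptides give 8 unique sites
  expect_equal(nrow(fixture_site_catalog("Table2")), 8L)

  # empty input gives an empty call set
  empty <- classify_peptides(
    obs_row("AAAAK", "R", "A", 5, E = 1, EQ = 1)[0, ],
    protease_rule("trypsin"))
  expect_equal(nrow(calls_from_semi(empty)), 0L)
})

test_that("raising the z threshold never increases the number of calls", {
  sim <- simulate_experiment(synthetic_config(seed = 19))
  obs <- sim$observations
  n_calls <- vapply(c(1, 1.5, 2, 2.5, 3, 4), function(th) {
    nrow(call_experiment(obs, z_threshold = th)$calls)
  }, 0)
  expect_true(all(diff(n_calls) <= 0))
})

test_that("abundance stratification tiers calls without dropping them", {
  # V1 evidence includes two significant peptides with log2 abundance
  # around 2.6, far below the bulk (17-21): they must be retained and
  # flagged as low-abundance outliers
  tab <- load_fixture("Table2")
  cl <- do.call(rbind, lapply(split(tab, tab$working_protease), function(b)
    classify_peptides(b, protease_rule(b$working_protease[1]))))
  cl$log2_abundance <- log2(pmax(cl$abundance_E, cl$abundance_EQ,
                                 na.rm = TRUE))
  fence <- abundance_fence(cl$log2_abundance)
  calls <- calls_from_semi(cl, enzyme = "ADAMTS9", fence = fence)
  expect_equal(nrow(calls), 8L)
  low <- calls[calls$tier == "outlier_low", ]
  expect_setequal(low$p1_pos, c(255L, 439L))
  expect_true(all(calls$tier[!calls$p1_pos %in% c(255, 439)] == "typical"))
})

test_that("EQ-enriched fully specific spanners corroborate contained calls", {
  proteins <- fixture_proteins()
  tab <- load_fixture("Table3")
  cl <- do.call(rbind, lapply(split(tab, tab$working_protease), function(b)
    classify_peptides(b, protease_rule(b$working_protease[1]))))
  calls <- deduplicate(calls_from_semi(cl, enzyme = "ADAMTS9",
                                       proteins = proteins))
  # spanning records constructed with the EQ-enriched direction (z < -2)
  span <- cl[cl$row_class == "spanning", ]
  span$z <- -10
  span$log2_abundance <- 18.5
  cal <- corroborate(calls, span)
  y1469 <- cal$calls[cal$calls$p1_pos == 1469L, ]
  expect_equal(y1469$n_spanning_peptides, 3L)   # all 1459-1480 variants
  n1463 <- cal$calls[cal$calls$p1_pos == 1463L, ]
  expect_equal(n1463$n_spanning_peptides, 3L)
  expect_equal(nrow(cal$orphans), 0L)

  # with no fully specific records calls are unchanged, no orphans
  cal0 <- corroborate(calls, span[0, ])
  expect_equal(cal0$calls$n_spanning_peptides, calls$n_spanning_peptides)
  expect_equal(nrow(cal0$orphans), 0L)

  # an EQ-enriched spanner over a call-free region becomes one orphan
  lone <- span[1, ]
  lone$start <- 100L; lone$end <- 121L
  cal1 <- corroborate(calls, lone)
  expect_equal(nrow(cal1$orphans), 1L)
  expect_true(all(cal1$calls$n_spanning_peptides ==
                    calls$n_spanning_peptides))
})
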