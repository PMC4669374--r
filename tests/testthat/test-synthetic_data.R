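test_that("colony simulator honours closed-form extremes and the seed contract", {
  point1 <- community_sim_params(fast_dist = c(1, rep(0, 9)),
                                 fast_fraction = 1, seed = 2)
  df <- simulate_colony_series(point1)
  idx <- colony_indices(df)
  expect_true(all(idx$cd == 100))
  expect_true(all(idx$ep == 0))

  # uniform slow class over all 10 days: mean CD near 10 * H_10
  unif <- community_sim_params(slow_dist = rep(0.1, 10), fast_fraction = 0,
                               expected_total = 400, seed = 3)
  idx_u <- colony_indices(simulate_colony_series(unif))
  expect_lt(abs(mean(idx_u$cd) - 29.2897), 0.5)

  # determinism: same seed, byte-identical CSV; different seed differs
  p <- community_sim_params(seed = 17)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  write_colony_counts(simulate_colony_series(p), f1)
  write_colony_counts(simulate_colony_series(p), f2)
  expect_identical(readLines(f1), readLines(f2))
  write_colony_counts(simulate_colony_series(community_sim_params(seed = 18)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("mean CD rises strictly with the fast-strategist fraction", {
  cds <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    p <- community_sim_params(fast_fraction = f, seed = 23)
    mean(colony_indices(simulate_colony_series(p))$cd)
  }, numeric(1))
  expect_true(all(diff(cds) > 0))
})

test_that("uniform emergence drives mean EP to its maximum with many colonies", {
  p <- community_sim_params(slow_dist = rep(0.1, 10), fast_fraction = 0,
                            expected_total = 12000, replicates = 1,
                            hydrocarbons = "naphthalene",
                            dose_multiplier = c(`0` = 1), seed = 29)
  idx <- colony_indices(simulate_colony_series(p))
  expect_lt(abs(mean(idx$ep) - 1), 0.02)
})

test_that("default cohort lands in the observed CD band and qualitative patterns", {
  f <- simulate_study(seed = 7, dir = tempfile())
  idx <- colony_indices(read_colony_counts(f[["colony"]]))
  expect_gt(mean(idx$cd), 26.38)
  expect_lt(mean(idx$cd), 27.27)
  recs <- read_activity_records(f[["activity"]])
  dr <- dose_response_summary(recs, analyte = "organotrophic_count")
  expect_true(all(dr$pearson_r > 0))          # counts rise with dose
  for (an in c("dehydrogenases", "urease")) {
    rt <- resistance_table(recs, analyte = an)
    expect_true(all(attr(rt, "summary")$pearson_r < 0))  # RS falls with dose
    expect_true(all(dose_response_summary(recs, analyte = an)$pearson_r < 0))
  }
})

test_that("enzyme simulator is exact at zero CV and recovers its slopes", {
  prm <- enzyme_sim_params(cv = 0, seed = 5)
  recs <- simulate_enzyme(prm)
  for (an in names(prm$analytes)) {
    spec <- prm$analytes[[an]]
    for (h in names(spec$slope)) {
      sub <- recs[recs$analyte == an & recs$hydrocarbon == h, ]
      expect_equal(sub$value,
                   pmax(0, spec$control_mean - spec$slope[[h]] * sub$dose_mg_per_kg),
                   tolerance = 1e-12)
      m <- tapply(sub$value, sub$dose_mg_per_kg, mean)
      fitted_slope <- (m[["0"]] - m[["4000"]]) / 4000
      expect_equal(unname(fitted_slope), unname(spec$slope[[h]]),
                   tolerance = 1e-12)
    }
  }
  # urease RS at 4000 recomputed from the calibrated defaults
  rt <- resistance_table(recs, analyte = "urease")
  rs4000 <- rt$rs[rt$dose_mg_per_kg == 4000 &
                    rt$hydrocarbon %in% c("naphthalene", "anthracene", "pyrene")]
  expect_true(all(rs4000 > 0.25 & rs4000 < 0.28))

  flat <- enzyme_sim_params(analytes = list(
    urease = list(control_mean = 2.76,
                  slope = c(naphthalene = 0, pyrene = 0))), cv = 0)
  rt0 <- resistance_table(simulate_enzyme(flat))
  expect_true(all(rt0$rs == 1))
})

test_that("phytotox simulator satisfies its closed forms and determinism", {
  # full germination, treated lengths equal control: SG = 0, RI ~ 0
  p_eq <- phytotox_sim_params(
    germination_prob = matrix(1, 3, 5, dimnames = list(
      c("Lepidium_sativum", "Sorghum_saccharatum", "Sinapis_alba"),
      c("control", pah_types()))),
    root_mean_mm = matrix(50, 3, 5, dimnames = list(
      c("Lepidium_sativum", "Sorghum_saccharatum", "Sinapis_alba"),
      c("control", pah_types()))),
    root_sd_mm = 0, seed = 11)
  res <- phytotox_summary(simulate_phytotox(p_eq))
  expect_true(all(res$sg_percent == 0))
  expect_true(all(abs(res$ri_percent) < 1e-9))

  # treated mean exactly 0.72 x control, sd 0: RI = 28 exactly
  m <- matrix(50, 3, 5, dimnames = dimnames(p_eq$root_mean_mm))
  m[, pah_types()] <- 36
  p_ri <- phytotox_sim_params(germination_prob = p_eq$germination_prob,
                              root_mean_mm = m, root_sd_mm = 0, seed = 11)
  res2 <- phytotox_summary(simulate_phytotox(p_ri))
  expect_equal(res2$ri_percent, rep(28, 12), tolerance = 1e-12)

  s1 <- simulate_phytotox(phytotox_sim_params(seed = 31))
  s2 <- simulate_phytotox(phytotox_sim_params(seed = 31))
  expect_identical(s1, s2)
})

test_that("simulator parameter objects validate their inputs", {
  expect_error(community_sim_params(fast_dist = c(0.5, rep(0, 9))),
               "invalid params")
  expect_error(community_sim_params(fast_fraction = 1.2), "invalid params")
  expect_error(enzyme_sim_params(cv = -0.1), "invalid params")
  expect_error(phytotox_sim_params(root_sd_mm = -1), "invalid params")
})
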