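test_that("resistance index reproduces printed and hand-computed values", {
  expect_equal(resistance_index(5, 5), 1)
  expect_equal(resistance_index(5, 0), 0)       # 100% impact
  expect_equal(round_half_up(resistance_index(8.63, 7.16), 3), 0.709)
  expect_equal(round_half_up(resistance_index(2.76, 1.63), 3), 0.419)
  # stimulation: |D0| = 0.31
  expect_equal(resistance_index(8.62, 8.93), 1 - 0.62 / 8.93,
               tolerance = 1e-12)
  expect_error(resistance_index(0, 1), "invalid control")
  expect_error(resistance_index(-2, 1), "invalid control")
})

test_that("resistance index is symmetric in disturbance sign and decreasing in size", {
  set.seed(51)
  for (k in 1:40) {
    c0 <- runif(1, 0.5, 10)
    delta <- runif(1, 0, c0)
    expect_equal(resistance_index(c0, c0 + delta),
                 resistance_index(c0, c0 - delta), tolerance = 1e-12)
    deltas <- sort(runif(5, 0, c0))
    rs <- resistance_index(c0, c0 - deltas)
    expect_true(all(diff(rs) < 1e-12))
    expect_true(all(rs > -1 & rs <= 1))
  }
})

test_that("treatment means reproduce the printed average rows", {
  counts <- printed_activity_means("organotrophic_count")
  naph <- counts$value[counts$hydrocarbon == "naphthalene"]
  expect_equal(treatment_mean(naph), 30.02, tolerance = 1e-12)
  ure <- printed_activity_means("urease")
  expect_equal(treatment_mean(ure$value[ure$hydrocarbon == "anthracene"]),
               1.86, tolerance = 1e-12)
  expect_equal(treatment_mean(7.5), 7.5)
  expect_error(treatment_mean(numeric(0)), "empty group")
})

test_that("fold changes reproduce the headline ratios", {
  expect_equal(round_half_up(fold_change(39.36, 18.25), 1), 2.2)
  expect_equal(round_half_up(fold_change(52.79, 18.25), 1), 2.9)
  expect_equal(fold_change(4, 4), 1)
  expect_error(fold_change(3, 0), "invalid control")
})

test_that("Pearson dose correlation matches direct evaluation and guards input", {
  doses <- c(0, 1000, 2000, 4000)
  expect_equal(pearson_dose_correlation(doses, doses * 2 + 1), 1)
  expect_equal(pearson_dose_correlation(doses, -doses + 100), -1)
  naph <- c(18.25, 23.25, 34.22, 44.36)
  expect_equal(round_half_up(pearson_dose_correlation(doses, naph), 3), 0.988)
  expect_error(pearson_dose_correlation(c(0, 1000), c(1, 2)), "3 dose levels")
  expect_error(pearson_dose_correlation(doses, rep(2, 4)), "zero variance")
})

test_that("dose-response summary columns carry control-normalized folds", {
  dr <- dose_response_summary(printed_activity_means("organotrophic_count"),
                              level = "mean")
  expect_equal(dr$fold_change[dr$dose == "0"], rep(1, 4))
  pyr <- dr[dr$hydrocarbon == "pyrene", ]
  expect_equal(pyr$mean[pyr$dose == "average"], 39.36, tolerance = 1e-12)
  expect_equal(round_half_up(pyr$fold_change[pyr$dose == "average"], 1), 2.2)
  # r is constant within a column and in [-1, 1]
  expect_true(all(abs(dr$pearson_r) <= 1))
})

test_that("resistance grid from printed means matches the printed table where reconcilable", {
  t5 <- load_printed_table("resistance")
  irreconcilable <- c("urease.phenanthrene.1000", "urease.phenanthrene.2000",
                      "urease.phenanthrene.4000",
                      "dehydrogenases.naphthalene.2000",
                      "dehydrogenases.naphthalene.4000",
                      "dehydrogenases.anthracene.1000",
                      "dehydrogenases.pyrene.1000")
  for (an in c("dehydrogenases", "urease")) {
    rt <- resistance_table(printed_activity_means(an))
    for (i in seq_len(nrow(rt))) {
      cell <- sprintf("%s.%s.%d", an, rt$hydrocarbon[i], rt$dose_mg_per_kg[i])
      printed <- t5$rs[t5$analyte == an &
                         t5$hydrocarbon == rt$hydrocarbon[i] &
                         t5$dose_mg_per_kg == rt$dose_mg_per_kg[i]]
      if (cell %in% irreconcilable) next
      expect_lt(abs(rt$rs[i] - printed), 0.003 + 1e-12, label = cell)
    }
  }
  # the flagged phenanthrene-urease column recomputes to a different level
  ure <- resistance_table(printed_activity_means("urease"))
  phen <- ure$rs[ure$hydrocarbon == "phenanthrene"]
  expect_equal(round_half_up(phen, 3), c(0.786, 0.353, 0.238))
})

test_that("replicate-paired resistance agrees with the mean route at zero noise", {
  recs <- simulate_enzyme(enzyme_sim_params(cv = 0, seed = 3))
  rt_mean <- resistance_table(recs, analyte = "urease")
  rt_pair <- resistance_table(recs, analyte = "urease", paired = TRUE)
  expect_equal(rt_pair$rs, rt_mean$rs, tolerance = 1e-12)
})
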