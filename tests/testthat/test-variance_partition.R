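test_that("two-way ANOVA matches the brute-force oracle and aov on random designs", {
  set.seed(71)
  for (k in 1:25) {
    a <- sample(2:4, 1); b <- sample(2:4, 1); n <- sample(2:5, 1)
    df <- random_balanced_design(a, b, n)
    fit <- two_way_anova(df)
    expect_equal(stats::setNames(fit$ss, fit$term), anova_ss_oracle(df),
                 tolerance = 1e-8)
    # independent route: stats::aov
    ref <- anova(stats::aov(value ~ factor(hydrocarbon) * factor(dose_mg_per_kg),
                            data = df))
    expect_equal(fit$ss, unname(ref$`Sum Sq`), tolerance = 1e-8)
    expect_equal(fit$df, unname(ref$Df))
    expect_equal(fit$f[1:3], unname(ref$`F value`[1:3]), tolerance = 1e-8)
    expect_equal(fit$p[1:3], unname(ref$`Pr(>F)`[1:3]), tolerance = 1e-8)
  }
})

test_that("ANOVA flags degenerate and structural edge cases", {
  df <- random_balanced_design(2, 2, 2)
  df$value <- 5
  fit <- two_way_anova(df)
  expect_true(attr(fit, "degenerate"))
  expect_equal(fit$ss, rep(0, 4))
  expect_error(eta_squared(fit), "degenerate variance")

  # pure dose effect, zero noise
  df2 <- expand.grid(hydrocarbon = c("h1", "h2"), dose_mg_per_kg = c(0, 1000),
                     replicate = 1:2, stringsAsFactors = FALSE)
  df2$value <- ifelse(df2$dose_mg_per_kg == 0, 1, 3)
  fit2 <- two_way_anova(df2)
  e2 <- eta_squared(fit2)
  expect_equal(unname(e2["dose"]), 100)
  expect_equal(fit2$ss[c(1, 3, 4)], rep(0, 3))

  unb <- random_balanced_design(2, 2, 3)[-1, ]
  expect_error(two_way_anova(unb), "unbalanced design")
  single <- random_balanced_design(2, 2, 1)
  expect_error(two_way_anova(single), "unbalanced design")
})

test_that("eta-squared shares sum to 100 and are affine-invariant", {
  set.seed(81)
  for (k in 1:10) {
    df <- random_balanced_design(3, 4, 3)
    e <- eta_squared(two_way_anova(df))
    expect_equal(sum(e), 100, tolerance = 1e-9)
    df2 <- df; df2$value <- -2.5 * df$value + 7
    expect_equal(eta_squared(two_way_anova(df2)), e, tolerance = 1e-9)
  }
})

test_that("eta shares reconstructed from printed count means land near the published partition", {
  means <- printed_activity_means("organotrophic_count")
  reps <- inject_replicates(means, error_share = 5.20, n = 3)
  fit <- two_way_anova(reps)
  e <- eta_squared(fit)
  expect_equal(unname(e["error"]), 5.20, tolerance = 1e-6)
  expect_lt(abs(e["dose"] - 63.59), 2)
  published <- load_printed_table("eta_squared")
  expect_equal(sum(published$organotrophic_count), 100, tolerance = 1e-9)
})

test_that("Tukey letters reproduce closed cases and printed column patterns", {
  # equal means share a letter
  cl <- tukey_letters(c(g1 = 2, g2 = 2), n = 3, ms_error = 0.5, df_error = 4)
  expect_equal(cl$letters, c("a", "a"))
  # separations far beyond the HSD threshold get distinct letters
  cl3 <- tukey_letters(c(a = 100, b = 50, c = 0), n = 3, ms_error = 1,
                       df_error = 6)
  expect_equal(cl3$letters, c("a", "b", "c"))
  expect_true(letters_match_decisions(cl3))

  # urease/pyrene column: means 2.76/2.22/1.63/1.14, sd 0.02, n = 3
  set.seed(91)
  mu <- c(2.76, 2.22, 1.63, 1.14)
  y <- rnorm(12, rep(mu, each = 3), sd = 0.02)
  gm <- tapply(y, rep(1:4, each = 3), mean)
  ms_e <- sum((y - rep(gm, each = 3))^2) / 8
  cl4 <- tukey_letters(stats::setNames(gm, paste0("d", 1:4)), n = 3,
                       ms_error = ms_e, df_error = 8, alpha = 0.01,
                       reverse = TRUE)
  expect_equal(cl4$letters, c("d", "c", "b", "a"))
  expect_true(letters_match_decisions(cl4))

  expect_error(tukey_letters(c(a = 1, b = 2), n = 3, ms_error = 0,
                             df_error = 4), "invalid variance")
})

test_that("letter sharing encodes non-significance exhaustively on random instances", {
  set.seed(101)
  for (k in 1:40) {
    g <- sample(3:8, 1)
    means <- stats::setNames(rnorm(g, sd = sample(c(0.3, 1, 3), 1)),
                             paste0("g", seq_len(g)))
    cl <- tukey_letters(means, n = 3, ms_error = runif(1, 0.05, 2),
                        df_error = 2 * g, alpha = 0.01)
    expect_true(letters_match_decisions(cl))
  }
})

test_that("raising the error variance only coarsens the letter display", {
  # pairs that share a letter at a smaller error variance still share one at
  # any larger error variance (non-significance is monotone in ms_error)
  set.seed(111)
  grid <- c(0.01, 0.1, 1, 10, 100)
  for (k in 1:10) {
    means <- stats::setNames(rnorm(5, sd = 2), paste0("g", 1:5))
    displays <- lapply(grid, function(mse) {
      tukey_letters(means, n = 3, ms_error = mse, df_error = 10)
    })
    for (m in seq_along(grid)[-1]) {
      lo <- displays[[m - 1]]; hi <- displays[[m]]
      for (i in 1:4) {
        for (j in (i + 1):5) {
          if (shares_letter(lo$letters[i], lo$letters[j])) {
            expect_true(shares_letter(hi$letters[i], hi$letters[j]))
          }
        }
      }
    }
    # and at a huge variance everything collapses to a single class
    expect_equal(n_letter_classes(displays[[length(grid)]]), 1)
  }
})

test_that("Monte-Carlo studentized-range fallback approximates the exact quantile", {
  q_mc <- pahsoiltox:::qtukey_mc(0.99, nmeans = 4, df = 32,
                                 nsim = 4e4, seed = 2)
  q_ex <- stats::qtukey(0.99, 4, 32)
  expect_lt(abs(q_mc - q_ex) / q_ex, 0.05)
  cl_a <- tukey_letters(c(a = 10, b = 5, c = 0), n = 3, ms_error = 0.5,
                        df_error = 6, method = "monte-carlo", mc_seed = 4)
  expect_equal(cl_a$letters, c("a", "b", "c"))
})

test_that("per-column dose letters run off the pooled two-way error term", {
  recs <- simulate_enzyme(enzyme_sim_params(cv = 0.02, seed = 13))
  lets <- dose_letters(recs, analyte = "urease", alpha = 0.01)
  expect_equal(nrow(lets), 16)
  expect_equal(sort(unique(lets$dose_mg_per_kg)), c(0, 1000, 2000, 4000))
  # with a strong monotone decline the control never shares the top letter
  # with the highest dose
  for (h in unique(lets$hydrocarbon)) {
    sub <- lets[lets$hydrocarbon == h, ]
    expect_false(shares_letter(sub$letters[sub$dose_mg_per_kg == 0],
                               sub$letters[sub$dose_mg_per_kg == 4000]))
  }
})
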