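# Independent brute-force oracles used to cross-check the implementation.

# Shannon entropy (base 10) computed directly from a count vector.
entropy_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log10(p))
}

# Two-way ANOVA sums of squares by explicit mean subtraction with loops
# over factor levels and cells (balanced designs).
anova_ss_oracle <- function(df) {
  y <- df$value
  A <- as.character(df$hydrocarbon)
  B <- as.character(df$dose_mg_per_kg)
  grand <- mean(y)
  ss_a <- 0
  for (a in unique(A)) ss_a <- ss_a + sum(A == a) * (mean(y[A == a]) - grand)^2
  ss_b <- 0
  for (b in unique(B)) ss_b <- ss_b + sum(B == b) * (mean(y[B == b]) - grand)^2
  ss_ab <- 0; ss_e <- 0
  for (a in unique(A)) {
    for (b in unique(B)) {
      sel <- A == a & B == b
      cm <- mean(y[sel])
      ss_ab <- ss_ab + sum(sel) *
        (cm - mean(y[A == a]) - mean(y[B == b]) + grand)^2
      ss_e <- ss_e + sum((y[sel] - cm)^2)
    }
  }
  c(type = ss_a, dose = ss_b, `type:dose` = ss_ab, error = ss_e)
}

# random balanced design with a x b cells and n replicates
random_balanced_design <- function(a, b, n, sd = 1) {
  grid <- expand.grid(hydrocarbon = paste0("h", seq_len(a)),
                      dose_mg_per_kg = seq_len(b) * 1000,
                      replicate = seq_len(n),
                      stringsAsFactors = FALSE)
  cell_mu <- stats::rnorm(a * b, sd = 3)
  key <- interaction(grid$hydrocarbon, grid$dose_mg_per_kg)
  grid$value <- cell_mu[as.integer(key)] + stats::rnorm(nrow(grid), sd = sd)
  grid
}

# do two groups of a letter display share at least one letter?
shares_letter <- function(l1, l2) {
  length(intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]])) > 0
}

# exhaustive check of the "share a letter <=> not significantly different"
# biconditional for a tukey_letters() result
letters_match_decisions <- function(cl) {
  sig <- attr(cl, "significant")
  k <- nrow(cl)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (shares_letter(cl$letters[i], cl$letters[j]) == sig[i, j]) return(FALSE)
    }
  }
  TRUE
}

n_letter_classes <- function(cl) {
  length(unique(unlist(strsplit(cl$letters, ""))))
}
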