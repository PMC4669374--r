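#' Balanced two-way ANOVA with interaction
#'
#' Classical sum-of-squares decomposition for a balanced, complete crossed
#' design (hydrocarbon type x dose with n replicates per cell):
#' \deqn{SS_{total} = SS_A + SS_B + SS_{AB} + SS_{error}}
#' with \eqn{F = MS_{term}/MS_{error}} and p-values from the F distribution.
#' Because the design is balanced, the decomposition is unique and the
#' Type-I/II/III distinction does not arise; unbalanced input is an error.
#'
#' @param data Data frame of replicate-level values.
#' @param value,type,dose Column names of the response and the two factors.
#' @return Object of class `pah_anova`: a data frame with rows `type`,
#'   `dose`, `type:dose`, `error` and columns `ss, df, ms, f, p`, plus
#'   attributes `grand_mean`, `cell_n`, `ms_error`, `df_error` and
#'   `degenerate` (`TRUE` when all values are identical, in which case eta
#'   squared is undefined).
#' @seealso [eta_squared()], [tukey_letters()]
#' @export
two_way_anova <- function(data, value = "value", type = "hydrocarbon",
                          dose = "dose_mg_per_kg") {
  check_columns(data, c(value, type, dose), "ANOVA input")
  y <- data[[value]]
  A <- factor(data[[type]])
  B <- factor(data[[dose]])
  if (any(!is.finite(y))) stop("ANOVA input contains non-finite values",
                               call. = FALSE)
  counts <- table(A, B)
  n <- counts[1L]
  if (any(counts != n)) {
    stop("unbalanced design: every type x dose cell must have the same number of replicates",
         call. = FALSE)
  }
  if (n < 2L) {
    stop("unbalanced design: need >= 2 replicates per cell to estimate error",
         call. = FALSE)
  }
  a <- nlevels(A); b <- nlevels(B)
  grand <- mean(y)
  mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  cell <- tapply(y, list(A, B), mean)
  ss_a <- b * n * sum((mA - grand)^2)
  ss_b <- a * n * sum((mB - grand)^2)
  ss_ab <- n * sum((cell - outer(mA, mB, "+") + grand)^2)
  ss_e <- sum((y - cell[cbind(A, B)])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (n - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_e)
  ms <- ss / df
  f <- if (ms[4L] > 0) ms[1:3] / ms[4L] else rep(NA_real_, 3L)
  p <- stats::pf(f, df[1:3], df[4L], lower.tail = FALSE)
  out <- data.frame(term = c("type", "dose", "type:dose", "error"),
                    ss = ss, df = df, ms = ms,
                    f = c(f, NA_real_), p = c(p, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "grand_mean") <- grand
  attr(out, "cell_n") <- as.integer(n)
  attr(out, "ms_error") <- ms[4L]
  attr(out, "df_error") <- df[4L]
  attr(out, "degenerate") <- sum(ss) <= 0
  class(out) <- c("pah_anova", "data.frame")
  out
}

#' Eta-squared variance shares
#'
#' Percentage of the total sum of squares attributable to each ANOVA term,
#' \eqn{\eta^2_{term} = 100 \cdot SS_{term} / SS_{total}}. Shares over the
#' four terms (two main effects, interaction, error) sum to 100.
#'
#' @param anova A `pah_anova` object from [two_way_anova()].
#' @return Named numeric vector of percentages.
#' @export
eta_squared <- function(anova) {
  stopifnot(inherits(anova, "pah_anova"))
  total <- sum(anova$ss)
  if (isTRUE(attr(anova, "degenerate")) || total <= 0) {
    stop("degenerate variance: all values identical, eta squared is undefined",
         call. = FALSE)
  }
  stats::setNames(100 * anova$ss / total, anova$term)
}

# Monte-Carlo quantile of the studentized range, a seeded fallback for
# stats::qtukey; simulates range(Z_1..Z_k) / sqrt(chi2_df / df).
qtukey_mc <- function(p, nmeans, df, nsim = 2e4, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  z <- matrix(stats::rnorm(nsim * nmeans), nsim, nmeans)
  rng <- apply(z, 1L, function(r) diff(range(r)))
  s <- sqrt(stats::rchisq(nsim, df) / df)
  stats::quantile(rng / s, probs = p, names = FALSE)
}

#' Tukey HSD homogeneous groups as a compact letter display
#'
#' Pairwise Tukey honestly-significant-difference decisions at level `alpha`
#' using the studentized range, turned into the letter annotations of
#' treatment tables by the insert-and-absorb compact-letter-display
#' algorithm. Two groups share at least one letter exactly when their means
#' are not significantly different.
#'
#' @param means Named numeric vector of group means (names become group
#'   labels).
#' @param n Common per-group sample size.
#' @param ms_error Error mean square from the ANOVA, > 0.
#' @param df_error Error degrees of freedom.
#' @param alpha Significance level (0.01 in the reproduced tables).
#' @param method `"exact"` uses [stats::qtukey()]; `"monte-carlo"` a seeded
#'   simulation fallback of the studentized-range quantile.
#' @param reverse Letters are assigned scanning means in descending order
#'   (default), so the largest mean carries "a"; `reverse = TRUE` scans
#'   ascending, the convention of the reproduced tables where the smallest
#'   mean carries "a". Ties in means are broken by input order.
#' @param mc_seed,mc_nsim Seed and size of the Monte-Carlo fallback.
#' @return Data frame `group, mean, letters` (input order), with attributes
#'   `hsd` (the minimum significant difference) and `significant` (logical
#'   pairwise decision matrix).
#' @examples
#' tukey_letters(c(a = 10, b = 5, c = 1), n = 3, ms_error = 0.1, df_error = 6)
#' @export
tukey_letters <- function(means, n, ms_error, df_error, alpha = 0.01,
                          method = c("exact", "monte-carlo"), reverse = FALSE,
                          mc_seed = 1L, mc_nsim = 2e4) {
  method <- match.arg(method)
  k <- length(means)
  if (k < 2L) stop("need >= 2 groups for a letter display", call. = FALSE)
  if (!is.finite(ms_error) || ms_error <= 0) {
    stop("invalid variance: 'ms_error' must be > 0", call. = FALSE)
  }
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  q <- switch(method,
              exact = stats::qtukey(1 - alpha, k, df_error),
              `monte-carlo` = qtukey_mc(1 - alpha, k, df_error,
                                        nsim = mc_nsim, seed = mc_seed))
  hsd <- q * sqrt(ms_error / n)
  signif <- abs(outer(means, means, "-")) > hsd
  diag(signif) <- FALSE
  ord <- order(if (reverse) means else -means)  # stable: ties keep input order
  cols <- cld_insert_absorb(signif[ord, ord, drop = FALSE])
  lab <- make_letters(length(cols))
  lets <- vapply(seq_len(k), function(i) {
    paste0(lab[vapply(cols, function(cc) cc[i], logical(1))], collapse = "")
  }, character(1))
  out <- data.frame(group = names(means), mean = unname(means),
                    letters = lets[match(seq_len(k), ord)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "hsd") <- hsd
  attr(out, "significant") <- signif
  out
}

# Insert-and-absorb compact letter display.
# signif: logical k x k matrix (groups already in display order).
# Returns a list of logical membership vectors, one per letter column;
# a significant pair never shares a column, a non-significant pair always
# shares at least one (both properties follow from the insertion step).
cld_insert_absorb <- function(signif) {
  k <- nrow(signif)
  cols <- list(rep(TRUE, k))
  pairs <- which(signif & upper.tri(signif), arr.ind = TRUE)
  if (nrow(pairs) > 0L) {
    # process in display order for determinism
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    hit <- vapply(cols, function(cc) cc[i] && cc[j], logical(1))
    if (!any(hit)) next
    keep <- cols[!hit]
    for (cc in cols[hit]) {
      ci <- cc; ci[i] <- FALSE
      cj <- cc; cj[j] <- FALSE
      keep <- c(keep, list(ci), list(cj))
    }
    # absorb columns that are subsets of another
    drop <- rep(FALSE, length(keep))
    for (u in seq_along(keep)) {
      for (v in seq_along(keep)) {
        if (u != v && !drop[v] &&
            all(keep[[u]] <= keep[[v]]) && any(keep[[u]] < keep[[v]])) {
          drop[u] <- TRUE
          break
        }
      }
    }
    # deduplicate identical columns
    sig <- vapply(keep, function(cc) paste0(as.integer(cc), collapse = ""),
                  character(1))
    drop <- drop | duplicated(sig)
    cols <- keep[!drop]
  }
  # order columns by their first member so letters read top-down
  firsts <- vapply(cols, function(cc) which(cc)[1L], integer(1))
  cols[order(firsts)]
}

#' Per-column dose letters for an activity table
#'
#' Reproduces the within-column annotations of the activity/count tables:
#' for each hydrocarbon, the four dose means are compared by Tukey's test
#' using the error mean square of the full balanced two-way fit.
#'
#' @inheritParams dose_response_summary
#' @param alpha Significance level.
#' @param reverse Passed to [tukey_letters()]; `TRUE` matches the printed
#'   convention (smallest mean = "a").
#' @return Data frame `hydrocarbon, dose_mg_per_kg, mean, letters`.
#' @export
dose_letters <- function(records, analyte = NULL, alpha = 0.01,
                         reverse = TRUE) {
  if (!is.null(analyte) && "analyte" %in% names(records)) {
    records <- records[records$analyte == analyte, , drop = FALSE]
  }
  fit <- two_way_anova(records)
  n <- attr(fit, "cell_n")
  out <- lapply(sort(unique(records$hydrocarbon)), function(h) {
    sub <- records[records$hydrocarbon == h, , drop = FALSE]
    m <- tapply(sub$value, sub$dose_mg_per_kg, mean)
    m <- m[order(as.numeric(names(m)))]
    cl <- tukey_letters(m, n = n, ms_error = attr(fit, "ms_error"),
                        df_error = attr(fit, "df_error"), alpha = alpha,
                        reverse = reverse)
    data.frame(hydrocarbon = h, dose_mg_per_kg = as.numeric(cl$group),
               mean = cl$mean, letters = cl$letters, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Replicates from cell means by symmetric residual injection
#'
#' Expands a table of cell means into n pseudo-replicates per cell with a
#' deterministic, zero-mean residual pattern whose size is chosen so the
#' error term takes a requested share of the total sum of squares. Used to
#' study how eta-squared shares computed from published cell means depend on
#' the (unpublished) residual variance, and to letter mean-only tables;
#' outputs are synthetic by construction.
#'
#' @param means Data frame with columns `hydrocarbon, dose_mg_per_kg, value`
#'   (one row per cell).
#' @param error_share Desired eta-squared share of the error term, percent.
#' @param n Replicates per cell (>= 3; the pattern needs (-d, 0, +d)).
#' @return Data frame of replicate-level records with the same factor
#'   columns, suitable for [two_way_anova()].
#' @export
inject_replicates <- function(means, error_share, n = 3L) {
  check_columns(means, c("hydrocarbon", "dose_mg_per_kg", "value"),
                "cell means")
  if (error_share <= 0 || error_share >= 100) {
    stop("'error_share' must be a percentage in (0, 100)", call. = FALSE)
  }
  if (n < 3L || n %% 2L == 0L) {
    stop("'n' must be an odd integer >= 3", call. = FALSE)
  }
  reps <- means[rep(seq_len(nrow(means)), each = n), , drop = FALSE]
  reps$replicate <- rep(seq_len(n), times = nrow(means))
  base <- seq_len(n) - (n + 1) / 2            # e.g. -1, 0, 1
  pattern <- rep(base, times = nrow(means))
  # model SS from means replicated n times; solve for d so that
  # SS_error / (SS_model + SS_error) = error_share / 100
  y0 <- rep(means$value, each = n)
  ss_model <- sum((y0 - mean(y0))^2)
  ss_error_target <- error_share / (100 - error_share) * ss_model
  d <- sqrt(ss_error_target / (nrow(means) * sum(base^2)))
  reps$value <- y0 + d * pattern
  rownames(reps) <- NULL
  reps
}
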