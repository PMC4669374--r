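#' Colony development (CD) index
#'
#' Weights early-appearing colonies more heavily:
#' \deqn{CD = 100 \sum_{i=1}^{D} f_i / i}
#' where \eqn{f_i} is the fraction of all colonies that first appeared on day
#' \eqn{i} of the \eqn{D}-day observation window. CD is 100 when every colony
#' appears on day 1 (fast, r-strategist-dominated communities) and 100/D when
#' every colony appears on day D, so CD lies in \[100/D, 100\].
#'
#' The source formula is sometimes written with day counts "expressed as a
#' percentage" together with a factor of 100, which would scale to 10,000 and
#' contradict the stated 0-100 range; proportions are used here, the
#' range-consistent reading.
#'
#' @param counts Non-negative vector of newly appeared colonies per day
#'   (day 1 first). Length defines the window D (default design: 10 days).
#' @return CD value in \[100/length(counts), 100\].
#' @examples
#' cd_index(c(50, 30, 20, rep(0, 7)))  # 71.67
#' cd_index(rep(1, 10))                # 29.29, uniform emergence
#' @export
cd_index <- function(counts) {
  f <- daily_fractions(counts)
  100 * sum(f / seq_along(f))
}

#' Ecophysiological diversity (EP) index
#'
#' Shannon entropy (base 10 by default) of the daily colony-appearance
#' proportions:
#' \deqn{EP = -\sum_i p_i \log_{10} p_i}
#' with the convention \eqn{0 \log 0 = 0}. EP is 0 when all colonies appear
#' on a single day and \eqn{\log_{10} D} for perfectly uniform emergence, so
#' for the default 10-day window EP ranges over \[0, 1\].
#'
#' @inheritParams cd_index
#' @param base Logarithm base; 10 matches the index definition. Pass
#'   `exp(1)` explicitly for a natural-log variant.
#' @return EP value in \[0, log(D, base)\].
#' @examples
#' ep_index(c(5, 5))     # log10(2) = 0.30103
#' ep_index(rep(3, 10))  # 1, maximum for a 10-day window
#' @export
ep_index <- function(counts, base = 10) {
  p <- daily_fractions(counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Per-plate CD and EP indices from a long colony table
#'
#' @param df Long-format data frame as produced by [read_colony_counts()] or
#'   [simulate_colony_series()].
#' @param days Observation window length D; series are padded with zero
#'   counts up to `days` (default 10).
#' @return Data frame with one row per plate: sample_id, hydrocarbon,
#'   dose_mg_per_kg, replicate, total, cd, ep.
#' @export
colony_indices <- function(df, days = 10) {
  check_columns(df, c("sample_id", "hydrocarbon", "dose_mg_per_kg",
                      "replicate", "day", "new_colonies"), "colony data")
  if (any(df$day > days)) {
    stop(sprintf("colony data contains day > %d; increase 'days'", days),
         call. = FALSE)
  }
  key <- interaction(df$sample_id, df$hydrocarbon, df$dose_mg_per_kg,
                     df$replicate, drop = TRUE, sep = "\r")
  out <- lapply(split(df, key), function(plate) {
    counts <- numeric(days)
    counts[plate$day] <- counts[plate$day] + plate$new_colonies
    data.frame(sample_id = plate$sample_id[1L],
               hydrocarbon = plate$hydrocarbon[1L],
               dose_mg_per_kg = plate$dose_mg_per_kg[1L],
               replicate = plate$replicate[1L],
               total = sum(counts),
               cd = cd_index(counts),
               ep = ep_index(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$hydrocarbon, out$dose_mg_per_kg, out$replicate), , drop = FALSE]
}

#' Group means and standard deviations of CD and EP
#'
#' @param idx Data frame from [colony_indices()].
#' @param by Grouping column, typically `"hydrocarbon"`.
#' @return Data frame of group, n, mean and sample standard deviation of each
#'   index. For singleton groups the standard deviation is reported as 0 by
#'   convention.
#' @export
index_summary <- function(idx, by = "hydrocarbon") {
  check_columns(idx, c(by, "cd", "ep"), "index results")
  if (nrow(idx) == 0L) stop("empty group: no index results", call. = FALSE)
  g <- factor(idx[[by]], levels = unique(idx[[by]]))
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  out <- data.frame(
    group = levels(g),
    n = as.vector(table(g)),
    cd_mean = as.vector(tapply(idx$cd, g, mean)),
    cd_sd = as.vector(tapply(idx$cd, g, sd0)),
    ep_mean = as.vector(tapply(idx$ep, g, mean)),
    ep_sd = as.vector(tapply(idx$ep, g, sd0)),
    stringsAsFactors = FALSE
  )
  names(out)[1L] <- by
  out
}
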