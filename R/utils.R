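#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used by
#' the printed tables this package reproduces), as opposed to base R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.285, 2)  # 0.29, where round() gives 0.28
#' round_half_up(-1.25, 1)  # -1.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon absorbs binary-representation error in x * p (e.g. 0.285*100)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Hydrocarbon and dose levels of the experimental design
#'
#' The four model PAHs and four contamination doses (mg per kg soil dry
#' matter) used throughout; dose 0 is the shared uncontaminated control.
#'
#' @return Character vector of hydrocarbons, or numeric vector of doses.
#' @export
pah_types <- function() c("naphthalene", "phenanthrene", "anthracene", "pyrene")

#' @rdname pah_types
#' @export
pah_doses <- function() c(0, 1000, 2000, 4000)

# Derive a reproducible substream seed from a master seed and an index, so
# per-plate / per-record streams are stable under partial re-runs.
# Kept strictly below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(index) * 16807 + 1) %% 2147483629)
}

# Check that a data frame has the named columns; error names the missing ones.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# letters, then aa, ab, ... for compact letter displays needing > 26 symbols
make_letters <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  extra <- as.vector(t(outer(letters, letters, paste0)))
  c(letters, extra)[seq_len(n)]
}
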