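#' Colony-forming units per kg soil dry matter
#'
#' Converts a dilution plate count to colony-forming units (cfu) per kilogram
#' of soil dry matter:
#' \deqn{cfu = a \cdot n \cdot \frac{100}{\%DM} \cdot 10^3}
#' where `a` is the number of colonies on the plate, `n` the inverse of the
#' dilution factor plated (e.g. `1e5` for a 10^-5 dilution), `100/%DM` the
#' dry-matter correction and `10^3` the per-kilogram conversion (counts are
#' plated from 1 cm^3 of suspension made from grams of fresh soil).
#'
#' @param colonies Non-negative number of colonies counted on the plate.
#' @param dilution_inverse Positive inverse of the dilution factor.
#' @param dry_matter_percent Soil dry-matter content, in (0, 100].
#' @return cfu per kg soil DM; zero exactly when `colonies` is zero.
#' @examples
#' cfu_count(120, 1e5, 92)  # 1.3043e10
#' @export
cfu_count <- function(colonies, dilution_inverse, dry_matter_percent) {
  if (any(!is.finite(colonies)) || any(colonies < 0)) {
    stop("invalid input: 'colonies' must be a non-negative count", call. = FALSE)
  }
  if (any(!is.finite(dilution_inverse)) || any(dilution_inverse <= 0)) {
    stop("invalid input: 'dilution_inverse' must be positive", call. = FALSE)
  }
  if (any(!is.finite(dry_matter_percent)) || any(dry_matter_percent <= 0) ||
      any(dry_matter_percent > 100)) {
    stop("invalid input: 'dry_matter_percent' must be in (0, 100]", call. = FALSE)
  }
  colonies * dilution_inverse * (100 / dry_matter_percent) * 1e3
}

#' Daily colony-appearance fractions
#'
#' Normalizes a vector of newly appeared colony counts (one entry per
#' observation day) to proportions of the total, the common input of the
#' colony development and ecophysiological diversity indices.
#'
#' @param counts Non-negative numeric vector, `counts[i]` = colonies first
#'   seen on day `i`.
#' @return Vector of proportions summing to 1.
#' @seealso [cd_index()], [ep_index()]
#' @export
daily_fractions <- function(counts) {
  if (length(counts) == 0L || any(!is.finite(counts)) || any(counts < 0)) {
    stop("invalid input: 'counts' must be a non-empty non-negative vector",
         call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("empty series: all daily colony counts are zero; CD/EP are undefined",
         call. = FALSE)
  }
  counts / total
}

#' Read or write a long-format colony-appearance CSV
#'
#' Schema: `sample_id, hydrocarbon, dose_mg_per_kg, replicate, day,
#' new_colonies` (UTF-8, comma-separated, header row); one row per plate and
#' observation day.
#'
#' @param path CSV file path.
#' @param df Data frame in the schema above (for writing).
#' @return The validated data frame (reader), or `path` invisibly (writer).
#' @export
read_colony_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "hydrocarbon", "dose_mg_per_kg",
                      "replicate", "day", "new_colonies"),
                what = sprintf("colony counts file '%s'", path))
  if (any(df$new_colonies < 0)) {
    stop("colony counts file contains negative 'new_colonies'", call. = FALSE)
  }
  if (any(df$day < 1)) stop("'day' must be >= 1", call. = FALSE)
  df
}

#' @rdname read_colony_counts
#' @export
write_colony_counts <- function(df, path) {
  check_columns(df, c("sample_id", "hydrocarbon", "dose_mg_per_kg",
                      "replicate", "day", "new_colonies"), "colony counts")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
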