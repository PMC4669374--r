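#' Percent inhibition relative to control
#'
#' The Phytotoxkit score for both endpoints (seed germination SG and root
#' growth RI):
#' \deqn{I = \frac{A - B}{A} \cdot 100}
#' where A is the control metric and B the treated metric. 0 means no effect,
#' 100 complete inhibition; negative values indicate stimulation. The score
#' is invariant to rescaling both A and B, so counts and percentages give
#' identical results for germination.
#'
#' @param a Control metric, strictly positive.
#' @param b Treated metric, non-negative.
#' @return Percent inhibition, <= 100.
#' @examples
#' inhibition_percent(50.0, 61.6)  # -23.2, stimulation
#' @export
inhibition_percent <- function(a, b) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("invalid control: 'a' must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(b)) || any(b < 0)) {
    stop("invalid input: 'b' must be non-negative", call. = FALSE)
  }
  (a - b) / a * 100
}

#' Read a Phytotoxkit trial CSV
#'
#' Schema: `species, hydrocarbon, dose_mg_per_kg, replicate, seeds_sown,
#' seeds_germinated, root_length_mm`. Rows may be per-seed (one germinated
#' seed per row, plate totals repeated) or per-plate aggregates
#' (`root_length_mm` = mean root length of the plate's germinated seeds).
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_phytotox_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("species", "hydrocarbon", "dose_mg_per_kg", "replicate",
                      "seeds_sown", "seeds_germinated", "root_length_mm"),
                what = sprintf("phytotoxicity file '%s'", path))
  if (any(df$seeds_germinated > df$seeds_sown, na.rm = TRUE) ||
      any(df$seeds_germinated < 0, na.rm = TRUE)) {
    stop("'seeds_germinated' must lie in [0, seeds_sown]", call. = FALSE)
  }
  df
}

# collapse per-seed or per-plate rows of one species x treatment to
# (total germinated over plates, mean root length of germinated seeds)
aggregate_trial <- function(sub) {
  key <- interaction(sub$replicate, drop = TRUE)
  per_plate <- lapply(split(sub, key), function(p) {
    germ <- max(p$seeds_germinated)   # repeated on per-seed rows
    lens <- p$root_length_mm[!is.na(p$root_length_mm)]
    c(germ = germ, len_sum = if (nrow(p) > 1L) sum(lens) else lens * germ,
      len_n = if (nrow(p) > 1L) length(lens) else germ)
  })
  m <- do.call(rbind, per_plate)
  c(germinated = sum(m[, "germ"]),
    root_mean = sum(m[, "len_sum"]) / max(sum(m[, "len_n"]), 1L))
}

#' Seed-germination and root-growth inhibition per species and hydrocarbon
#'
#' Compares each species x hydrocarbon treatment (dose > 0) against the
#' shared dose-0 control of the same species. The germination metric is the
#' total number of germinated seeds over the replicate plates; the root
#' metric is the mean root length of germinated seeds.
#'
#' @param trials Data frame as from [read_phytotox_trials()] or
#'   [simulate_phytotox()].
#' @return Data frame with columns `species, hydrocarbon, a_germinated,
#'   b_germinated, sg_percent, a_root_mm, b_root_mm, ri_percent`.
#' @export
phytotox_summary <- function(trials) {
  check_columns(trials, c("species", "hydrocarbon", "dose_mg_per_kg",
                          "replicate", "seeds_sown", "seeds_germinated",
                          "root_length_mm"), "phytotoxicity trials")
  out <- list()
  for (sp in unique(trials$species)) {
    sub <- trials[trials$species == sp, , drop = FALSE]
    ctrl <- sub[sub$dose_mg_per_kg == 0, , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      stop(sprintf("invalid control: species '%s' has no dose-0 trials", sp),
           call. = FALSE)
    }
    a <- aggregate_trial(ctrl)
    trt <- sub[sub$dose_mg_per_kg > 0, , drop = FALSE]
    for (h in unique(trt$hydrocarbon)) {
      b <- aggregate_trial(trt[trt$hydrocarbon == h, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        species = sp, hydrocarbon = h,
        a_germinated = a[["germinated"]], b_germinated = b[["germinated"]],
        sg_percent = inhibition_percent(a[["germinated"]], b[["germinated"]]),
        a_root_mm = a[["root_mean"]], b_root_mm = b[["root_mean"]],
        ri_percent = inhibition_percent(a[["root_mean"]], b[["root_mean"]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean inhibition of one species over the four hydrocarbons
#'
#' @param results Data frame with columns `species, hydrocarbon` and the
#'   metric column (e.g. from [phytotox_summary()] or a transcription of a
#'   printed inhibition table).
#' @param species Species to summarize.
#' @param metric Metric column name, `"sg_percent"` or `"ri_percent"`.
#' @return Mean percent over the four hydrocarbons.
#' @export
species_mean_inhibition <- function(results, species,
                                    metric = c("ri_percent", "sg_percent")) {
  metric <- match.arg(metric)
  check_columns(results, c("species", "hydrocarbon", metric),
                "inhibition results")
  sub <- results[results$species == species, , drop = FALSE]
  missing <- setdiff(pah_types(), sub$hydrocarbon)
  if (length(missing) > 0L) {
    stop(sprintf("incomplete design: species '%s' is missing hydrocarbon(s) %s",
                 species, paste(missing, collapse = ", ")), call. = FALSE)
  }
  mean(sub[[metric]][match(pah_types(), sub$hydrocarbon)])
}

#' Mean inhibition of one hydrocarbon over the three test species
#'
#' @inheritParams species_mean_inhibition
#' @param hydrocarbon Hydrocarbon to summarize.
#' @param species_set The full species panel that must be present.
#' @return Mean percent over the species panel.
#' @export
hydrocarbon_mean_inhibition <- function(results, hydrocarbon,
                                        metric = c("ri_percent", "sg_percent"),
                                        species_set = c("Lepidium_sativum",
                                                        "Sorghum_saccharatum",
                                                        "Sinapis_alba")) {
  metric <- match.arg(metric)
  check_columns(results, c("species", "hydrocarbon", metric),
                "inhibition results")
  sub <- results[results$hydrocarbon == hydrocarbon, , drop = FALSE]
  missing <- setdiff(species_set, sub$species)
  if (length(missing) > 0L) {
    stop(sprintf("incomplete design: hydrocarbon '%s' is missing species %s",
                 hydrocarbon, paste(missing, collapse = ", ")), call. = FALSE)
  }
  mean(sub[[metric]][match(species_set, sub$species)])
}
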