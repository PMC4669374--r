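#' Packaged transcriptions of the published treatment tables
#'
#' The package ships plain-CSV transcriptions of the printed treatment-mean
#' tables of the source study (organotrophic counts, dehydrogenase and urease
#' activities, resistance indices, microbial group counts, phytotoxicity
#' inhibition percentages, and the eta-squared shares), used by
#' [reproduce_tables()] and the acceptance checks. They contain means only;
#' no replicate-level raw data were published.
#'
#' @param table One of `"counts"`, `"dehydrogenases"`, `"urease"`,
#'   `"resistance"`, `"microbial_groups"`, `"phytotox_inhibition"`,
#'   `"eta_squared"`, `"reference"`.
#' @return The table as a data frame.
#' @export
load_printed_table <- function(table = c("counts", "dehydrogenases", "urease",
                                         "resistance", "microbial_groups",
                                         "phytotox_inhibition", "eta_squared",
                                         "reference")) {
  table <- match.arg(table)
  file <- switch(table,
                 counts = "table2_organotrophic_counts.csv",
                 dehydrogenases = "table3_dehydrogenases.csv",
                 urease = "table4_urease.csv",
                 resistance = "table5_resistance.csv",
                 microbial_groups = "table6_microbial_groups.csv",
                 phytotox_inhibition = "table8_phytotox_inhibition.csv",
                 eta_squared = "table1_eta_squared.csv",
                 reference = "printed_reference.csv")
  path <- system.file("extdata", file, package = "pahsoiltox", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop(sprintf("fixture error: '%s' is empty; reinstall the package", file),
         call. = FALSE)
  }
  df
}

#' Printed treatment means as activity records
#'
#' Convenience reshaping of the mean tables into the long activity-record
#' layout (`analyte, hydrocarbon, dose_mg_per_kg, value`; no replicate
#' column, since only means were published).
#'
#' @param analyte `"organotrophic_count"`, `"dehydrogenases"` or `"urease"`.
#' @return Long data frame of cell means.
#' @export
printed_activity_means <- function(analyte = c("organotrophic_count",
                                               "dehydrogenases", "urease")) {
  analyte <- match.arg(analyte)
  tab <- load_printed_table(switch(analyte,
                                   organotrophic_count = "counts",
                                   dehydrogenases = "dehydrogenases",
                                   urease = "urease"))
  data.frame(analyte = analyte, hydrocarbon = tab$hydrocarbon,
             dose_mg_per_kg = tab$dose_mg_per_kg, value = tab$value,
             stringsAsFactors = FALSE)
}

#' Printed inhibition percentages as a results table
#'
#' Reshapes the phytotoxicity fixture into the layout of
#' [phytotox_summary()] output (`sg_percent` / `ri_percent` columns) so the
#' species- and hydrocarbon-level summaries can run on the printed values.
#'
#' @return Data frame `species, hydrocarbon, sg_percent, ri_percent`.
#' @export
printed_inhibition_results <- function() {
  tab <- load_printed_table("phytotox_inhibition")
  sg <- tab[tab$metric == "sg", ]
  ri <- tab[tab$metric == "ri", ]
  key <- paste(sg$species, sg$hydrocarbon)
  ri_val <- ri$value[match(key, paste(ri$species, ri$hydrocarbon))]
  data.frame(species = sg$species, hydrocarbon = sg$hydrocarbon,
             sg_percent = sg$value, ri_percent = ri_val,
             stringsAsFactors = FALSE)
}
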