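#' Run the full analysis pipeline on study CSVs
#'
#' Reads the three study inputs (any subset), runs every stage — colony
#' indices, dose-response summaries, soil resistance, two-way ANOVA with
#' eta-squared shares and Tukey letter displays, and phytotoxicity scoring —
#' and writes one CSV per stage into `out_dir` plus a small run log (package
#' version, alpha, input checksums).
#'
#' @param colony,activity,phytotox File paths (or data frames already in the
#'   respective schemas); `NULL` skips the stage.
#' @param out_dir Output directory, created if needed.
#' @param alpha Significance level for the letter displays.
#' @param days Colony observation window.
#' @return Invisibly, a named list with every computed table.
#' @export
analyze_study <- function(colony = NULL, activity = NULL, phytotox = NULL,
                          out_dir = "pahsoiltox_results", alpha = 0.01,
                          days = 10) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  inputs <- character()
  emit <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }

  if (!is.null(colony)) {
    if (is.character(colony)) { inputs <- c(inputs, colony); colony <- read_colony_counts(colony) }
    idx <- colony_indices(colony, days = days)
    results$colony_indices <- idx
    results$index_summary <- index_summary(idx)
    emit(idx, "colony_indices")
    emit(results$index_summary, "index_summary")
  }

  if (!is.null(activity)) {
    if (is.character(activity)) { inputs <- c(inputs, activity); activity <- read_activity_records(activity) }
    analytes <- unique(activity$analyte)
    dr <- list(); rs <- list(); rs_sum <- list(); eta <- list(); lets <- list()
    anova_rows <- list()
    for (an in analytes) {
      dr[[an]] <- cbind(analyte = an,
                        dose_response_summary(activity, analyte = an))
      rt <- resistance_table(activity, analyte = an)
      rs[[an]] <- cbind(analyte = an, as.data.frame(rt))
      rs_sum[[an]] <- cbind(analyte = an, attr(rt, "summary"))
      fit <- two_way_anova(activity[activity$analyte == an, , drop = FALSE])
      anova_rows[[an]] <- cbind(analyte = an, as.data.frame(fit))
      eta[[an]] <- data.frame(analyte = an, term = fit$term,
                              eta_squared_percent = as.numeric(eta_squared(fit)))
      lets[[an]] <- cbind(analyte = an,
                          dose_letters(activity, analyte = an, alpha = alpha))
    }
    results$dose_response <- do.call(rbind, dr)
    results$resistance <- do.call(rbind, rs)
    results$resistance_summary <- do.call(rbind, rs_sum)
    results$anova <- do.call(rbind, anova_rows)
    results$eta_squared <- do.call(rbind, eta)
    results$letters <- do.call(rbind, lets)
    for (nm in c("dose_response", "resistance", "resistance_summary",
                 "anova", "eta_squared", "letters")) {
      rownames(results[[nm]]) <- NULL
      emit(results[[nm]], nm)
    }
  }

  if (!is.null(phytotox)) {
    if (is.character(phytotox)) { inputs <- c(inputs, phytotox); phytotox <- read_phytotox_trials(phytotox) }
    ph <- phytotox_summary(phytotox)
    results$phytotox <- ph
    emit(ph, "phytotox_summary")
  }

  log_lines <- c(
    sprintf("pahsoiltox %s", utils::packageVersion("pahsoiltox")),
    sprintf("alpha: %g; days: %d", alpha, days),
    if (length(inputs)) sprintf("input %s md5 %s", inputs,
                                unname(tools::md5sum(inputs)))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
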