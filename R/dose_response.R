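#' Orwin-Wardle soil resistance index
#'
#' Resistance of a soil property to a disturbance, computed at the assessment
#' time from the control value \eqn{C_0} and the value in the disturbed soil
#' \eqn{P(t_0)}:
#' \deqn{RS(t_0) = 1 - \frac{2|D_0|}{C_0 + |D_0|}, \qquad D_0 = C_0 - P(t_0)}
#' RS is 1 when the stressor had no effect, 0 when the impact equals 100% of
#' the control (e.g. the property dropped to zero) and approaches -1 as the
#' impact approaches 200%. The absolute value makes stimulation
#' (\eqn{P > C_0}) and inhibition of equal size score identically.
#'
#' @param c0 Control value(s), strictly positive.
#' @param p_t0 Value(s) in the disturbed soil at assessment time, >= 0.
#' @return RS value(s) in (-1, 1].
#' @examples
#' resistance_index(8.63, 7.16)  # 0.709, dehydrogenases under pyrene
#' resistance_index(2.76, 1.14)  # 0.260
#' @export
resistance_index <- function(c0, p_t0) {
  if (any(!is.finite(c0)) || any(c0 <= 0)) {
    stop("invalid control: 'c0' must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(p_t0)) || any(p_t0 < 0)) {
    stop("invalid input: 'p_t0' must be non-negative", call. = FALSE)
  }
  d0 <- abs(c0 - p_t0)
  1 - 2 * d0 / (c0 + d0)
}

#' Fold change relative to the uncontaminated control
#'
#' @param treated Treated mean (or value).
#' @param control Control mean, strictly positive.
#' @return `treated / control`; 1 when treated equals control.
#' @export
fold_change <- function(treated, control) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop("invalid control: control mean must be strictly positive",
         call. = FALSE)
  }
  treated / control
}

#' Arithmetic mean of a treatment group
#'
#' Thin, validating mean used for dose-level and per-column averages (the
#' per-hydrocarbon column mean is the mean of the four dose-level means,
#' control included).
#'
#' @param values Numeric vector, at least one value.
#' @return Arithmetic mean.
#' @export
treatment_mean <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop("empty group: no values to average", call. = FALSE)
  }
  mean(values)
}

#' Pearson correlation between dose and response
#'
#' Product-moment correlation of an activity/count against the contamination
#' dose, at replicate level or on dose means.
#'
#' @param doses Numeric dose vector (paired with `values`).
#' @param values Numeric response vector.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_dose_correlation <- function(doses, values) {
  ok <- is.finite(doses) & is.finite(values)
  doses <- doses[ok]; values <- values[ok]
  if (length(unique(doses)) < 3L) {
    stop("need data at >= 3 dose levels for a dose correlation", call. = FALSE)
  }
  if (stats::sd(doses) == 0 || stats::sd(values) == 0) {
    stop("undefined correlation: zero variance in dose or response",
         call. = FALSE)
  }
  stats::cor(doses, values)
}

#' Read an activity/count CSV
#'
#' Schema: `analyte, hydrocarbon, dose_mg_per_kg, replicate, value`.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_activity_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("analyte", "hydrocarbon", "dose_mg_per_kg",
                      "replicate", "value"),
                what = sprintf("activity file '%s'", path))
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    stop("activity file contains negative or non-finite 'value'",
         call. = FALSE)
  }
  df
}

# dose-level means of one analyte: hydrocarbon x dose table (rows = doses)
dose_mean_table <- function(records, analyte = NULL) {
  check_columns(records, c("hydrocarbon", "dose_mg_per_kg", "value"),
                "activity records")
  if (!is.null(analyte)) {
    if ("analyte" %in% names(records)) {
      records <- records[records$analyte == analyte, , drop = FALSE]
    }
    if (nrow(records) == 0L) {
      stop(sprintf("empty group: no records for analyte '%s'", analyte),
           call. = FALSE)
    }
  }
  tab <- tapply(records$value,
                list(dose = records$dose_mg_per_kg,
                     hydrocarbon = records$hydrocarbon),
                mean)
  tab[order(as.numeric(rownames(tab))), , drop = FALSE]
}

#' Dose-response summary for one analyte
#'
#' Per hydrocarbon: dose-level means, the column mean (mean of the dose-level
#' means, control included), fold changes versus the dose-0 control of the
#' same column, and the Pearson correlation of the response against dose.
#'
#' @param records Data frame with columns `hydrocarbon, dose_mg_per_kg,
#'   replicate, value` (and optionally `analyte`).
#' @param analyte Optional analyte to filter on.
#' @param level Level at which the dose correlation is computed:
#'   `"replicate"` (default when replicate data exist) or `"mean"`
#'   (dose-level means).
#' @return Data frame, one row per hydrocarbon x dose plus an
#'   `dose = "average"` row per hydrocarbon, with columns `mean`,
#'   `fold_change` and `pearson_r` (r repeated within a column).
#' @export
dose_response_summary <- function(records, analyte = NULL,
                                  level = c("auto", "replicate", "mean")) {
  level <- match.arg(level)
  if (!is.null(analyte) && "analyte" %in% names(records)) {
    records <- records[records$analyte == analyte, , drop = FALSE]
  }
  tab <- dose_mean_table(records)
  doses <- as.numeric(rownames(tab))
  if (!any(doses == 0)) {
    stop("invalid control: no dose-0 rows to serve as control", call. = FALSE)
  }
  has_reps <- "replicate" %in% names(records) &&
    any(table(records$hydrocarbon, records$dose_mg_per_kg) > 1L)
  if (level == "auto") level <- if (has_reps) "replicate" else "mean"
  out <- lapply(colnames(tab), function(h) {
    m <- tab[, h]
    ctrl <- m[doses == 0]
    r <- if (level == "replicate") {
      sub <- records[records$hydrocarbon == h, , drop = FALSE]
      pearson_dose_correlation(sub$dose_mg_per_kg, sub$value)
    } else {
      pearson_dose_correlation(doses, m)
    }
    data.frame(hydrocarbon = h,
               dose = c(as.character(doses), "average"),
               mean = c(m, mean(m)),
               fold_change = c(m, mean(m)) / ctrl,
               pearson_r = r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Soil-resistance table from treatment means
#'
#' Computes the Orwin-Wardle resistance index for every hydrocarbon x dose
#' (> 0) cell of one analyte, using the dose-0 mean of the same hydrocarbon
#' column as control, plus a per-column average RS and the Pearson
#' correlation of RS against dose. This is the mean-level computation used
#' for reported tables; see `paired` for a replicate-paired variant.
#'
#' @inheritParams dose_response_summary
#' @param paired If `TRUE`, RS is computed per replicate (replicate r of a
#'   treated cell against replicate r of the control) and then averaged;
#'   default `FALSE` (means first).
#' @return Data frame with columns `hydrocarbon, dose_mg_per_kg, c0, p_t0,
#'   d0, rs`, plus attribute `"summary"` holding per-column average RS and r.
#' @export
resistance_table <- function(records, analyte = NULL, paired = FALSE) {
  if (!is.null(analyte) && "analyte" %in% names(records)) {
    records <- records[records$analyte == analyte, , drop = FALSE]
  }
  tab <- dose_mean_table(records)
  doses <- as.numeric(rownames(tab))
  if (!any(doses == 0)) {
    stop("invalid control: no dose-0 rows to serve as control", call. = FALSE)
  }
  treated_doses <- doses[doses > 0]
  rows <- lapply(colnames(tab), function(h) {
    c0 <- tab[doses == 0, h]
    p <- tab[match(treated_doses, doses), h]
    rs <- if (!paired) {
      resistance_index(c0, p)
    } else {
      sub <- records[records$hydrocarbon == h, , drop = FALSE]
      ctrl <- sub[sub$dose_mg_per_kg == 0, , drop = FALSE]
      vapply(treated_doses, function(d) {
        trt <- sub[sub$dose_mg_per_kg == d, , drop = FALSE]
        idx <- match(trt$replicate, ctrl$replicate)
        if (anyNA(idx)) {
          stop("replicate-paired RS needs matching replicate ids in control",
               call. = FALSE)
        }
        mean(resistance_index(ctrl$value[idx], trt$value))
      }, numeric(1))
    }
    data.frame(hydrocarbon = h, dose_mg_per_kg = treated_doses,
               c0 = c0, p_t0 = p, d0 = c0 - p, rs = rs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(split(out, out$hydrocarbon), function(s) {
    r <- tryCatch(pearson_dose_correlation(s$dose_mg_per_kg, s$rs),
                  error = function(e) NA_real_)  # constant RS has no slope
    data.frame(hydrocarbon = s$hydrocarbon[1L],
               rs_average = mean(s$rs),
               pearson_r = r,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}
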