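#' Parameters for the colony-appearance simulator
#'
#' The community is a two-class mixture of colonizing strategies: a fast
#' (r-strategist) class whose colonies appear early and a slow (K-strategist)
#' class appearing late. Defaults emulate the study design (10-day window,
#' 4 hydrocarbons x 4 doses x 3 replicate plates) with a fast fraction of
#' 0.2, which puts the closed-form mean CD at 26.9, inside the 26.4-27.3
#' band observed for the real communities, and with colony totals rising
#' with dose as observed for organotrophic counts.
#'
#' @param days Observation window D.
#' @param fast_dist,slow_dist Appearance-day distributions of the two
#'   classes (length `days`, each summing to 1).
#' @param fast_fraction Probability that a colony belongs to the fast class.
#' @param expected_total Expected colonies per control plate.
#' @param dose_multiplier Named multiplier of the expected total per dose.
#' @param hydrocarbons,replicates Design factors.
#' @param seed Master seed; all randomness derives from it via per-plate
#'   substreams.
#' @return Validated parameter list of class `community_sim_params`.
#' @export
community_sim_params <- function(days = 10,
                                 fast_dist = c(0.5, 0.3, 0.2, rep(0, days - 3)),
                                 slow_dist = c(rep(0, 3), rep(1 / (days - 3), days - 3)),
                                 fast_fraction = 0.2,
                                 expected_total = 200,
                                 dose_multiplier = c(`0` = 1, `1000` = 1.5,
                                                     `2000` = 2, `4000` = 2.5),
                                 hydrocarbons = pah_types(),
                                 replicates = 3,
                                 seed = 1L) {
  stopifnot(days >= 1, length(fast_dist) == days, length(slow_dist) == days)
  if (any(fast_dist < 0) || any(slow_dist < 0) ||
      abs(sum(fast_dist) - 1) > 1e-8 || abs(sum(slow_dist) - 1) > 1e-8) {
    stop("invalid params: appearance distributions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (fast_fraction < 0 || fast_fraction > 1) {
    stop("invalid params: 'fast_fraction' must lie in [0, 1]", call. = FALSE)
  }
  if (expected_total <= 0 || any(dose_multiplier <= 0)) {
    stop("invalid params: expected totals must be positive", call. = FALSE)
  }
  structure(list(days = days, fast_dist = fast_dist, slow_dist = slow_dist,
                 fast_fraction = fast_fraction,
                 expected_total = expected_total,
                 dose_multiplier = dose_multiplier,
                 hydrocarbons = hydrocarbons,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "community_sim_params")
}

#' Simulate colony-appearance series
#'
#' Per plate, the total colony count is Poisson around the dose-scaled
#' expected total; each colony is assigned to the fast class with probability
#' `fast_fraction` and its appearance day is drawn from the class
#' distribution. Identical seeds give identical output (per-plate
#' substreams), so partial re-runs are stable.
#'
#' @param params A [community_sim_params()] object.
#' @return Long data frame in the [read_colony_counts()] schema.
#' @export
simulate_colony_series <- function(params = community_sim_params()) {
  stopifnot(inherits(params, "community_sim_params"))
  doses <- as.numeric(names(params$dose_multiplier))
  grid <- expand.grid(replicate = seq_len(params$replicates),
                      dose_mg_per_kg = doses,
                      hydrocarbon = params$hydrocarbons,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    set.seed(derive_seed(params$seed, i))
    mult <- params$dose_multiplier[[as.character(g$dose_mg_per_kg)]]
    total <- stats::rpois(1L, params$expected_total * mult)
    n_fast <- stats::rbinom(1L, total, params$fast_fraction)
    counts <- numeric(params$days)
    if (n_fast > 0) {
      counts <- counts + stats::rmultinom(1L, n_fast, params$fast_dist)[, 1L]
    }
    if (total - n_fast > 0) {
      counts <- counts + stats::rmultinom(1L, total - n_fast,
                                          params$slow_dist)[, 1L]
    }
    rows[[i]] <- data.frame(
      sample_id = sprintf("%s_%d_r%d", substr(g$hydrocarbon, 1, 3),
                          g$dose_mg_per_kg, g$replicate),
      hydrocarbon = g$hydrocarbon, dose_mg_per_kg = g$dose_mg_per_kg,
      replicate = g$replicate, day = seq_len(params$days),
      new_colonies = counts, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameters for the enzyme/count simulator
#'
#' Activities decline linearly in dose from the control mean (floored at
#' zero), with multiplicative log-normal noise of a given coefficient of
#' variation. Default control means and per-hydrocarbon slopes are
#' calibrated to the printed dehydrogenase and urease treatment means
#' (controls 8.63 and 2.76; urease declining to 1.1-1.2 at 4000 mg kg-1),
#' and organotrophic counts rise with dose instead (negative "slope").
#'
#' @param analytes Named list: for each analyte, `control_mean` and a named
#'   per-hydrocarbon `slope` (activity units per mg kg-1; positive = decline).
#' @param cv Replicate coefficient of variation (>= 0).
#' @param doses,replicates Design factors.
#' @param seed Master seed.
#' @return Validated parameter list of class `enzyme_sim_params`.
#' @export
enzyme_sim_params <- function(analytes = list(
                                dehydrogenases = list(
                                  control_mean = 8.63,
                                  slope = c(naphthalene = 6.025e-4,
                                            phenanthrene = 8.675e-4,
                                            anthracene = 1.9e-4,
                                            pyrene = 3.675e-4)),
                                urease = list(
                                  control_mean = 2.76,
                                  slope = c(naphthalene = 4.125e-4,
                                            phenanthrene = 4.25e-4,
                                            anthracene = 3.95e-4,
                                            pyrene = 4.05e-4)),
                                organotrophic_count = list(
                                  control_mean = 18.25,
                                  slope = c(naphthalene = -6.5e-3,
                                            phenanthrene = -3.2e-3,
                                            anthracene = -1.14e-2,
                                            pyrene = -8.6e-3))),
                              cv = 0.05,
                              doses = pah_doses(),
                              replicates = 3,
                              seed = 1L) {
  for (nm in names(analytes)) {
    an <- analytes[[nm]]
    if (is.null(an$control_mean) || an$control_mean <= 0) {
      stop(sprintf("invalid params: analyte '%s' needs control_mean > 0", nm),
           call. = FALSE)
    }
    if (is.null(names(an$slope))) {
      stop(sprintf("invalid params: analyte '%s' needs a named slope vector", nm),
           call. = FALSE)
    }
  }
  if (cv < 0) stop("invalid params: 'cv' must be >= 0", call. = FALSE)
  structure(list(analytes = analytes, cv = cv, doses = doses,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "enzyme_sim_params")
}

#' Simulate enzyme activities and bacterial counts
#'
#' @param params An [enzyme_sim_params()] object.
#' @return Data frame in the [read_activity_records()] schema.
#' @export
simulate_enzyme <- function(params = enzyme_sim_params()) {
  stopifnot(inherits(params, "enzyme_sim_params"))
  sdlog <- sqrt(log(1 + params$cv^2))
  rows <- list()
  idx <- 0L
  for (an in names(params$analytes)) {
    spec <- params$analytes[[an]]
    for (h in names(spec$slope)) {
      for (d in params$doses) {
        idx <- idx + 1L
        set.seed(derive_seed(params$seed, idx))
        base <- max(0, spec$control_mean - spec$slope[[h]] * d)
        noise <- if (sdlog > 0) {
          stats::rlnorm(params$replicates, meanlog = -sdlog^2 / 2,
                        sdlog = sdlog)
        } else rep(1, params$replicates)
        rows[[idx]] <- data.frame(
          analyte = an, hydrocarbon = h, dose_mg_per_kg = d,
          replicate = seq_len(params$replicates),
          value = base * noise, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameters for the Phytotoxkit simulator
#'
#' Per species x treatment: a per-seed germination probability and a
#' truncated-at-zero normal root-length distribution. Defaults place the
#' treated dose at 4000 mg kg-1 (the dose used in the assay) with
#' germination probabilities and root-length means derived from the printed
#' inhibition percentages, so the expected SG/RI of a large simulation
#' matches the printed table.
#'
#' @param species Species panel.
#' @param germination_prob Matrix (species x treatments incl. "control") of
#'   per-seed germination probabilities.
#' @param root_mean_mm Matrix of root-length means (mm), same layout.
#' @param root_sd_mm Root-length standard deviation (mm).
#' @param seeds_per_plate,plates Assay design (10 seeds, 3 plates).
#' @param dose_mg_per_kg Treated dose.
#' @param seed Master seed.
#' @return Validated parameter list of class `phytotox_sim_params`.
#' @export
phytotox_sim_params <- function(species = c("Lepidium_sativum",
                                            "Sorghum_saccharatum",
                                            "Sinapis_alba"),
                                germination_prob = default_germination_prob(),
                                root_mean_mm = default_root_mean_mm(),
                                root_sd_mm = 5,
                                seeds_per_plate = 10,
                                plates = 3,
                                dose_mg_per_kg = 4000,
                                seed = 1L) {
  if (any(germination_prob < 0) || any(germination_prob > 1)) {
    stop("invalid params: germination probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (root_sd_mm < 0 || any(root_mean_mm <= 0)) {
    stop("invalid params: root-length parameters must be positive",
         call. = FALSE)
  }
  structure(list(species = species, germination_prob = germination_prob,
                 root_mean_mm = root_mean_mm, root_sd_mm = root_sd_mm,
                 seeds_per_plate = as.integer(seeds_per_plate),
                 plates = as.integer(plates),
                 dose_mg_per_kg = dose_mg_per_kg, seed = as.integer(seed)),
            class = "phytotox_sim_params")
}

# Germination probabilities implied by the printed inhibition table at a
# fully germinating control.
default_germination_prob <- function() {
  sg <- rbind(Lepidium_sativum = c(20.0, 10.0, 0.0, 16.6),
              Sorghum_saccharatum = c(0.0, 0.0, 6.6, 0.0),
              Sinapis_alba = c(6.6, 0.0, 3.3, 16.6))
  p <- cbind(control = c(1, 1, 1), (100 - sg) / 100)
  colnames(p) <- c("control", pah_types())
  p
}

# Root-length means (mm) implied by the printed root-growth inhibition at
# species-typical control lengths.
default_root_mean_mm <- function() {
  ri <- rbind(Lepidium_sativum = c(16.2, 22.5, 16.4, 15.9),
              Sorghum_saccharatum = c(9.3, -1.25, -22.7, -23.2),
              Sinapis_alba = c(21.8, 40.4, 37.9, 11.9))
  ctrl <- c(Lepidium_sativum = 50, Sorghum_saccharatum = 40,
            Sinapis_alba = 30)
  m <- cbind(control = ctrl, ctrl * (100 - ri) / 100)
  colnames(m) <- c("control", pah_types())
  m
}

#' Simulate Phytotoxkit trials
#'
#' Germination is an independent Bernoulli draw per seed; root lengths of
#' germinated seeds are normal truncated at zero. Output is per-seed rows
#' (plates with zero germinated seeds emit one row with `NA` root length so
#' the plate is still represented).
#'
#' @param params A [phytotox_sim_params()] object.
#' @return Data frame in the [read_phytotox_trials()] schema.
#' @export
simulate_phytotox <- function(params = phytotox_sim_params()) {
  stopifnot(inherits(params, "phytotox_sim_params"))
  treatments <- colnames(params$germination_prob)
  rows <- list()
  idx <- 0L
  for (sp in params$species) {
    for (tr in treatments) {
      for (pl in seq_len(params$plates)) {
        idx <- idx + 1L
        set.seed(derive_seed(params$seed, idx))
        prob <- params$germination_prob[sp, tr]
        germ <- stats::rbinom(1L, params$seeds_per_plate, prob)
        mu <- params$root_mean_mm[sp, tr]
        lens <- if (germ > 0) {
          rtnorm_pos(germ, mu, params$root_sd_mm)
        } else NA_real_
        rows[[idx]] <- data.frame(
          species = sp,
          hydrocarbon = if (tr == "control") "control" else tr,
          dose_mg_per_kg = if (tr == "control") 0 else params$dose_mg_per_kg,
          replicate = pl,
          seeds_sown = params$seeds_per_plate,
          seeds_germinated = germ,
          root_length_mm = lens,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# normal truncated at zero via rejection (root lengths; mu >> sd in practice)
rtnorm_pos <- function(n, mu, sd) {
  if (sd == 0) return(rep(mu, n))
  x <- stats::rnorm(n, mu, sd)
  bad <- x < 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mu, sd)
    bad <- x < 0
  }
  x
}

#' Generate the full synthetic study
#'
#' Writes the three CSVs consumed by the pipeline (colony series, activity
#' records, phytotoxicity trials) plus a JSON manifest recording the seed,
#' the package version and the file checksums.
#'
#' @param seed Master seed (propagated to all three generators).
#' @param dir Output directory (created if needed).
#' @param community,enzyme,phytotox Optional parameter objects; their seeds
#'   are overridden by `seed`.
#' @return Named character vector of file paths, invisibly.
#' @export
simulate_study <- function(seed = 1L, dir = ".",
                           community = community_sim_params(),
                           enzyme = enzyme_sim_params(),
                           phytotox = phytotox_sim_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  community$seed <- as.integer(seed)
  enzyme$seed <- derive_seed(seed, 7919L)
  phytotox$seed <- derive_seed(seed, 104729L)
  files <- c(colony = file.path(dir, "colony_counts.csv"),
             activity = file.path(dir, "activity_records.csv"),
             phytotox = file.path(dir, "phytotox_trials.csv"))
  write_colony_counts(simulate_colony_series(community), files[["colony"]])
  utils::write.csv(simulate_enzyme(enzyme), files[["activity"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(simulate_phytotox(phytotox), files[["phytotox"]],
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "pahsoiltox",
    version = as.character(utils::packageVersion("pahsoiltox")),
    seed = as.integer(seed),
    design = list(days = community$days,
                  hydrocarbons = community$hydrocarbons,
                  doses = as.numeric(names(community$dose_multiplier)),
                  replicates = community$replicates),
    fast_fraction = community$fast_fraction,
    cv = enzyme$cv,
    md5 = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, manifest = file.path(dir, "manifest.json")))
}
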