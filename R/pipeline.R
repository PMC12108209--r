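#' Per-genotype, per-organ redox potential table
#'
#' Converts background-corrected per-seedling channel intensities to E_GSH
#' and summarizes per genotype and organ: mean, SD (the reporting
#' convention for redox potentials), n, and Duncan letters comparing
#' genotypes within each organ. Calibration is per imaging batch; a batch
#' without calibration is a hard error naming the batch.
#'
#' @param measurements Data frame with columns `genotype`, `organ`, `i405`,
#'   `i488` and optionally `batch` (default batch "1").
#' @param calibrations A [rogfp_calibration()] (applied to every batch) or
#'   a named list of them keyed by batch.
#' @param constants A [rogfp_constants()].
#' @param alpha Significance level for the letters.
#' @return Data frame of class `redox_table` with columns `genotype`,
#'   `organ`, `egsh_mean`, `egsh_sd`, `n`, `letters`; per-seedling values
#'   in attribute `"seedlings"`.
#' @export
run_redox_table <- function(measurements, calibrations,
                            constants = rogfp_constants(), alpha = 0.05) {
  need <- c("genotype", "organ", "i405", "i488")
  stopifnot(all(need %in% names(measurements)))
  if (is.null(measurements$batch)) measurements$batch <- "1"
  if (inherits(calibrations, "rogfp_calibration")) {
    calibrations <- stats::setNames(
      rep(list(calibrations), length(unique(measurements$batch))),
      unique(measurements$batch))
  }
  missing_cal <- setdiff(unique(measurements$batch), names(calibrations))
  if (length(missing_cal) > 0L) {
    stop("missing calibration for batch: ",
         paste(missing_cal, collapse = ", "), call. = FALSE)
  }
  measurements$egsh <- NA_real_
  measurements$oxd <- NA_real_
  measurements$clamped <- NA
  for (b in unique(measurements$batch)) {
    sel <- measurements$batch == b
    res <- egsh_from_intensities(measurements$i405[sel],
                                 measurements$i488[sel],
                                 calibrations[[b]], constants)
    measurements$egsh[sel] <- res$egsh
    measurements$oxd[sel] <- res$oxd
    measurements$clamped[sel] <- res$clamped
  }
  out <- list()
  for (org in unique(measurements$organ)) {
    sub <- measurements[measurements$organ == org, , drop = FALSE]
    by_gt <- split(sub$egsh, factor(sub$genotype,
                                    levels = unique(sub$genotype)))
    letters <- if (length(by_gt) >= 2L && all(lengths(by_gt) >= 2L)) {
      duncan_mrt(by_gt, alpha = alpha)$letters
    } else {
      stats::setNames(rep(NA_character_, length(by_gt)), names(by_gt))
    }
    out[[org]] <- data.frame(
      genotype = names(by_gt), organ = org,
      egsh_mean = round(vapply(by_gt, mean, numeric(1)), 2),
      egsh_sd = round(vapply(by_gt, stats::sd, numeric(1)), 2),
      n = lengths(by_gt),
      letters = unname(letters[names(by_gt)]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "seedlings") <- measurements
  class(out) <- c("redox_table", "data.frame")
  out
}

#' @export
print.redox_table <- function(x, ...) {
  cat("Glutathione redox potential (mV, mean ± SD, Duncan letters)\n")
  df <- data.frame(genotype = x$genotype, organ = x$organ,
                   egsh = sprintf("%.2f ± %.2f %s", x$egsh_mean,
                                  x$egsh_sd,
                                  ifelse(is.na(x$letters), "",
                                         x$letters)),
                   n = x$n)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Growth / ROS / vitality report with letters and correlation panels
#'
#' The phenotype statistics layer in one call: derives lateral root
#' density, expresses the dye-intensity traits as percent of the untreated
#' wild-type control, runs a one-way ANOVA plus Duncan's multiple range
#' test per trait over all genotype x treatment groups, and computes
#' per-genotype Pearson correlation matrices (pooling treatments within
#' genotype). Traits with zero variance are skipped with a warning.
#'
#' @param table Phenotype data frame (as from
#'   [generate_phenotype_table()]): columns `genotype`, `treatment`, and
#'   trait columns.
#' @param control_genotype,control_treatment Labels of the untreated
#'   wild-type control group (its mean maps to 100%).
#' @param intensity_traits Traits to normalize to percent of control.
#' @param alpha Significance level.
#' @return List of class `phenotype_report`: `summary` (long data frame:
#'   trait, genotype, treatment, mean, se, n, letters), `anova` (per-trait
#'   [duncan_mrt()] objects), `correlations` (per-genotype `cor_matrix`
#'   list), `overall_correlation`, `table` (augmented input).
#' @export
run_phenotype_report <- function(table, control_genotype = "Col-0",
                                 control_treatment = "control",
                                 intensity_traits = c("root_superoxide",
                                                      "root_ros",
                                                      "shoot_ros",
                                                      "root_vitality",
                                                      "shoot_vitality"),
                                 alpha = 0.05) {
  stopifnot(all(c("genotype", "treatment") %in% names(table)))
  if (all(c("lateral_root_count", "primary_root_length") %in%
          names(table))) {
    table$lateral_root_density <-
      lateral_root_density(table$lateral_root_count,
                           table$primary_root_length)
  }
  ctrl <- table$genotype == control_genotype &
    table$treatment == control_treatment
  if (!any(ctrl)) {
    stop("input error: no rows for the control group ", control_genotype,
         " / ", control_treatment, call. = FALSE)
  }
  for (v in intersect(intensity_traits, names(table))) {
    table[[v]] <- percent_of_control(table[[v]], table[[v]][ctrl])
  }
  traits <- intersect(c(phenotype_traits(), "lateral_root_density"),
                      names(table))
  grp <- interaction(table$genotype, table$treatment, sep = ":",
                     lex.order = TRUE, drop = TRUE)
  tests <- list()
  summaries <- list()
  for (v in traits) {
    if (stats::var(table[[v]]) == 0) {
      warning("trait ", v, " has zero variance; skipped", call. = FALSE)
      next
    }
    d <- duncan_mrt(split(table[[v]], grp), alpha = alpha)
    tests[[v]] <- d
    agg <- do.call(rbind, lapply(levels(grp), function(g) {
      vals <- table[[v]][grp == g]
      gt <- strsplit(g, ":", fixed = TRUE)[[1]]
      data.frame(trait = v, genotype = gt[1], treatment = gt[2],
                 mean = mean(vals),
                 se = stats::sd(vals) / sqrt(length(vals)),
                 n = length(vals), letters = unname(d$letters[g]),
                 stringsAsFactors = FALSE)
    }))
    summaries[[v]] <- agg
  }
  out <- list(summary = do.call(rbind, summaries),
              anova = tests,
              correlations = pearson_matrix(table, by = "genotype"),
              overall_correlation = pearson_matrix(table),
              table = table,
              alpha = alpha)
  rownames(out$summary) <- NULL
  class(out) <- "phenotype_report"
  out
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(sprintf("phenotype report: %d traits, %d groups, alpha = %g\n",
              length(x$anova), length(unique(paste(x$summary$genotype,
                                                   x$summary$treatment))),
              x$alpha))
  for (v in names(x$anova)) {
    a <- x$anova[[v]]$anova
    cat(sprintf("  %-22s F(%d,%d) = %8.2f, p = %.3g\n", v, a$df_between,
                a$df_error, a$f_statistic, a$p_value))
  }
  cat("correlation matrices for:",
      paste(names(x$correlations), collapse = ", "), "\n")
  invisible(x)
}

#' Run the full seeded pipeline from a config file
#'
#' Orchestrates simulation, quantification, the redox table and the
#' phenotype report from one YAML config, writing CSV outputs (each with a
#' header recording the seed and the config MD5) into `outdir`.
#'
#' Config keys (all optional): `constants` / `calibration` (see
#' [read_redox_config()]); `phenotype: {csv: <path>}` to analyse an
#' existing table, otherwise `phenotype: {n_per_group:, preset: gpxl}`
#' simulates one; `redox: {measurements_csv: <path>}` to analyse existing
#' per-seedling intensities, otherwise small biosensor scenes are
#' simulated from the reference potentials of
#' [reference_redox_potentials()] (`redox: {replicates:, dim:}`).
#'
#' @param config Path to a YAML config file (or a pre-parsed list).
#' @param seed Integer seed overriding the config's seed.
#' @param outdir Output directory (created if needed).
#' @return List of class `pipeline_run`: `redox_table`,
#'   `phenotype_report`, `seed`, `config_md5`, `files` (paths written).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, outdir = tempfile()) {
  config_md5 <- NA_character_
  if (is.character(config)) {
    config_md5 <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  seed <- as.integer(config$seed %||% seed)
  if (!is.null(config$seed_override)) seed <- as.integer(config$seed_override)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  constants <- do.call(rogfp_constants, config$constants %||% list())

  # phenotype arm
  pheno_cfg <- config$phenotype %||% list()
  pheno <- if (!is.null(pheno_cfg$csv)) {
    read_table_csv(pheno_cfg$csv)
  } else {
    generate_phenotype_table(
      phenotype_preset_gpxl(n_per_group = pheno_cfg$n_per_group %||% 45L,
                            seed = seed))
  }
  report <- run_phenotype_report(pheno)

  # redox arm
  redox_cfg <- config$redox %||% list()
  if (!is.null(redox_cfg$measurements_csv)) {
    meas <- read_table_csv(redox_cfg$measurements_csv)
    calib <- if (!is.null(config$calibration)) {
      do.call(rogfp_calibration, config$calibration)
    } else {
      stop("missing calibration for batch: ",
           paste(unique(meas$batch %||% "1"), collapse = ", "),
           call. = FALSE)
    }
    redox <- run_redox_table(meas, calib, constants)
  } else {
    redox <- simulate_redox_measurements(
      replicates = redox_cfg$replicates %||% 4L,
      dim = rep(redox_cfg$dim %||% 48L, 2L),
      seed = seed, constants = constants)
  }

  files <- c(
    redox = write_table_csv(as.data.frame(redox),
                            file.path(outdir, "redox_table.csv"),
                            seed, config_md5),
    phenotype = write_table_csv(report$summary,
                                file.path(outdir, "phenotype_summary.csv"),
                                seed, config_md5),
    correlations = write_table_csv(
      do.call(rbind, lapply(names(report$correlations), function(g) {
        cor_long(report$correlations[[g]], group = g)
      })),
      file.path(outdir, "correlations.csv"), seed, config_md5))
  out <- list(redox_table = redox, phenotype_report = report,
              seed = seed, config_md5 = config_md5, files = files)
  class(out) <- "pipeline_run"
  out
}

# Simulate per-seedling biosensor measurements at the reference potentials
# (one small two-channel scene per seedling) and build the redox table.
simulate_redox_measurements <- function(replicates = 4L, dim = c(48L, 48L),
                                        seed = 1L,
                                        constants = rogfp_constants()) {
  ref <- reference_redox_potentials()
  rows <- list()
  scene_seed <- seed
  for (i in seq_len(nrow(ref))) {
    oxd <- oxd_from_egsh(ref$egsh_mv[i], constants)
    for (r in seq_len(replicates)) {
      scene_seed <- scene_seed + 1L
      sc <- biosensor_scene(oxd = oxd, dim = dim, seed = scene_seed)
      stacks <- generate_biosensor_stack(sc)
      roi <- default_center_roi(stacks$sample)
      m <- ratio_measurement(stacks$sample, roi)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = ref$genotype[i], organ = ref$organ[i],
        batch = "synthetic", replicate = r,
        i405 = m$i405, i488 = m$i488, stringsAsFactors = FALSE)
    }
  }
  meas <- do.call(rbind, rows)
  # batch calibration from one zero-oxidation / full-oxidation scene pair
  sc <- biosensor_scene(oxd = 0.5, dim = dim, seed = seed)
  stacks <- generate_biosensor_stack(sc)
  calib <- estimate_calibration(stacks$calib_red, stacks$calib_ox)
  run_redox_table(meas, list(synthetic = calib), constants)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d, config md5 %s)\n", x$seed,
              x$config_md5))
  print(x$redox_table)
  print(x$phenotype_report)
  cat("outputs:\n")
  for (f in x$files) cat("  ", f, "\n")
  invisible(x)
}
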