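#' Read / write CSV tables with a provenance header
#'
#' Tables written by the pipeline carry a leading comment line
#' `# rogfp2 seed=<seed> config_md5=<hash>` recording the seed and the MD5
#' of the run config; `read_table_csv` skips such comment lines.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @param seed Seed recorded in the header (`NA` if none).
#' @param config_md5 Config file hash recorded in the header.
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv`
#'   returns a data frame.
#' @export
write_table_csv <- function(x, path, seed = NA, config_md5 = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rogfp2 seed=%s config_md5=%s",
                     as.character(seed), as.character(config_md5)), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Reference cytosolic redox potentials of Col-0 and gpxl mutant seedlings
#'
#' Published cytosolic glutathione redox potentials (mV, mean and SD with
#' Duncan letters) measured with a cytosolic roGFP2 probe in cotyledons and
#' root tips of 6-day-old Arabidopsis wild type (Col-0) and glutathione
#' peroxidase-like mutant (gpxl1-8) seedlings, shipped as a plain-text
#' reference table.
#'
#' @return Data frame with columns `genotype`, `organ`, `egsh_mv`, `sd_mv`,
#'   `letters`.
#' @export
reference_redox_potentials <- function() {
  read_table_csv(system.file("extdata", "seedling_redox_potentials.csv",
                             package = "rogfp2", mustWork = TRUE))
}
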