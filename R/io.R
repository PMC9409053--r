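# File I/O: CSV schemas with unit-suffixed column names, two-channel image
# pairs, and machine-readable provenance records.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

.read_csv_schema <- function(path, cols, what = path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, cols, what)
  df
}

#' Read assay and study CSV files with schema validation
#'
#' Readers for the package's CSV schemas; each checks its required
#' unit-suffixed columns and fails naming any missing one.
#' Schemas: DSB measurements (`dose_Gy`, `percent_dsb`), colony assays
#' (`dose_Gy`, `colonies`, `cells_seeded`; optional `activity_Bq`,
#' `replicate`, `group`), biodistribution (`organ`, `time_h`,
#' `value_pct_aa_g`; optional `unit`, `n`, `sd`), tumour growth (`group`,
#' `animal`, `day`, `relative_size`; optional `relative_weight`).
#'
#' @param path CSV file path.
#' @return A data frame.
#' @name read_schemas
NULL

#' @rdname read_schemas
#' @export
read_dsb_csv <- function(path) {
  .read_csv_schema(path, c("dose_Gy", "percent_dsb"))
}

#' @rdname read_schemas
#' @export
read_colony_csv <- function(path) {
  .read_csv_schema(path, c("dose_Gy", "colonies", "cells_seeded"))
}

#' @rdname read_schemas
#' @export
read_biodistribution_csv <- function(path) {
  .read_csv_schema(path, c("organ", "time_h", "value_pct_aa_g"))
}

#' @rdname read_schemas
#' @export
read_growth_csv <- function(path) {
  .read_csv_schema(path, c("group", "animal", "day", "relative_size"))
}

#' Write or read a two-channel image pair as TIFF
#'
#' Image pairs follow the naming convention `<id>_nuc.tif` / `<id>_dmg.tif`.
#' Intensities are clipped to `[0, 1]` and stored as 16-bit grayscale.
#'
#' @param nuclei,damage Numeric intensity matrices of equal shape.
#' @param path_prefix Path prefix `<dir>/<id>`; the two suffixed files are
#'   written next to it.
#' @return `write_image_pair` returns the two file paths invisibly;
#'   `read_image_pair` returns `list(nuclei, damage)` of matrices.
#' @export
write_image_pair <- function(nuclei, damage, path_prefix) {
  stopifnot(is.matrix(nuclei), is.matrix(damage),
            identical(dim(nuclei), dim(damage)))
  clip <- function(x) pmin(pmax(x, 0), 1)
  paths <- paste0(path_prefix, c("_nuc.tif", "_dmg.tif"))
  tiff::writeTIFF(clip(nuclei), paths[1L], bits.per.sample = 16L)
  tiff::writeTIFF(clip(damage), paths[2L], bits.per.sample = 16L)
  invisible(paths)
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(path_prefix) {
  paths <- paste0(path_prefix, c("_nuc.tif", "_dmg.tif"))
  for (p in paths) if (!file.exists(p)) stop("image file not found: ", p)
  list(nuclei = tiff::readTIFF(paths[1L]),
       damage = tiff::readTIFF(paths[2L]))
}

#' Write a machine-readable provenance record
#'
#' Every pipeline run writes a JSON record of its parameters, seeds and the
#' package version next to its outputs, so any result can be regenerated.
#'
#' @param path Output JSON path.
#' @param subcommand The pipeline stage name.
#' @param params Named list of all parameters (including seeds).
#' @return The path, invisibly.
#' @export
write_provenance <- function(path, subcommand, params) {
  rec <- list(subcommand = subcommand,
              package = "radbiodose",
              version = as.character(utils::packageVersion("radbiodose")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
              params = params)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
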