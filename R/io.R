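# Standard-format I/O: the feature-table CSV dialect and per-cell TIFF
# image sets with JSON sidecars.

feature_table_columns <- c("donor", "cell_id", "C", "HW", "L", "MW",
                           "VA", "AA", "DFI")

#' Write a feature table to CSV
#'
#' RFC 4180 CSV with the documented header
#' `donor,cell_id,C,HW,L,MW,VA,AA,DFI`; unit metadata (and any supplied
#' annotations such as a seed or config hash) are preserved as `#` comment
#' lines above the header. Extra columns are written untouched.
#'
#' @param table data.frame with at least the documented columns.
#' @param path output path.
#' @param comments optional named character vector of extra `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, comments = NULL) {
  validate_feature_table(table)
  extra <- setdiff(names(table), feature_table_columns)
  table <- table[c(feature_table_columns, extra)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# units: C, DFI dimensionless; HW, L, MW um; VA, AA um^2",
    if (!is.null(comments)) paste0("# ", names(comments), ": ", comments)
  ), con)
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Validates the documented columns and that DFI lies in `[0, 1]`
#' (violations name the offending row); extra columns are preserved. A
#' missing `ln_dfi` column is derived as `log(DFI)` (clipped away from 0
#' and 1).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  table <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  validate_feature_table(table)
  if (!"ln_dfi" %in% names(table)) {
    table$ln_dfi <- log(pmin(pmax(table$DFI, DFI_EPS), 1 - DFI_EPS))
  }
  table
}

validate_feature_table <- function(table) {
  missing <- setdiff(feature_table_columns, names(table))
  if (length(missing) > 0) {
    stop("SchemaError: missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(table$DFI) | table$DFI < 0 | table$DFI > 1)
  if (length(bad) > 0) {
    stop("validation error: DFI outside [0, 1] in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(table)
}

#' Write a cell image set as TIFFs with a JSON sidecar
#'
#' One 16-bit grayscale TIFF per channel (`<prefix>_brightfield.tif`,
#' `_green.tif`, `_red.tif`) plus `<prefix>.json` recording
#' `pixel_size_um` and any annotations (seed, config hash).
#'
#' @param images a `cell_image_set`.
#' @param prefix path prefix (directories must exist).
#' @param metadata named list merged into the sidecar.
#' @return the sidecar path, invisibly.
#' @export
write_cell_images <- function(images, prefix, metadata = list()) {
  for (ch in c("brightfield", "green", "red")) {
    tiff::writeTIFF(images[[ch]], paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 16L)
  }
  side <- c(list(pixel_size_um = images$pixel_size_um), metadata)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Read a cell image set written by [write_cell_images()]
#'
#' @param prefix the path prefix used when writing.
#' @return a `cell_image_set`.
#' @export
read_cell_images <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  chans <- lapply(c("brightfield", "green", "red"), function(ch) {
    tiff::readTIFF(paste0(prefix, "_", ch, ".tif"))
  })
  structure(list(brightfield = chans[[1]], green = chans[[2]],
                 red = chans[[3]],
                 pixel_size_um = side$pixel_size_um,
                 truth = side$truth %||% NULL),
            class = "cell_image_set")
}
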