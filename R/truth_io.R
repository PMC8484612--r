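.truth_columns <- c("id", "x_um", "y_um", "z_um", "length_um", "diameter_um",
                    "axis_x", "axis_y", "axis_z")

#' Write ground truth (cell table + label volume) to disk
#'
#' Cells go to a CSV (`columns id, x_um, y_um, z_um, length_um,
#' diameter_um, axis_x, axis_y, axis_z, reflectivity`), the label volume
#' to a 16-bit multi-page TIFF with JSON sidecar.
#'
#' @param truth A `ground_truth` from [rasterize_cells()].
#' @param cells_csv Path for the cell table.
#' @param labels_tiff Optional path for the label volume (skipped if
#'   `NULL`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_truth <- function(truth, cells_csv, labels_tiff = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- truth$cells[, c(.truth_columns, "reflectivity")]
  write.csv(df, cells_csv, row.names = FALSE)
  out <- c(cells = cells_csv)
  if (!is.null(labels_tiff)) {
    write_labels(truth$labels, labels_tiff)
    out <- c(out, labels = labels_tiff)
  }
  invisible(out)
}

#' Read ground truth written by [write_truth()]
#'
#' @param cells_csv Path to the cell table CSV.
#' @param labels_tiff Optional path to the label-volume TIFF.
#' @param spec Optional [scene_spec()] to attach.
#' @return A `ground_truth` (with `labels = NULL` if no TIFF given).
#' @export
read_truth <- function(cells_csv, labels_tiff = NULL, spec = NULL) {
  if (!file.exists(cells_csv)) stop("no such file: ", cells_csv)
  df <- read.csv(cells_csv)
  missing_cols <- setdiff(.truth_columns, names(df))
  if (length(missing_cols))
    stop("ground-truth CSV ", cells_csv, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(df$reflectivity)) df$reflectivity <- 1
  bad <- which(!stats::complete.cases(df[, .truth_columns]))
  if (length(bad))
    stop("ground-truth CSV ", cells_csv, " has malformed row(s): line ",
         paste(bad + 1L, collapse = ", "))
  if (!is.null(spec)) attr(df, "spec") <- spec
  class(df) <- c("cell_set", "data.frame")
  labels <- if (!is.null(labels_tiff)) read_labels(labels_tiff) else NULL
  structure(list(cells = df, labels = labels, spec = spec),
            class = "ground_truth")
}
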