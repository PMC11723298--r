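# Export of sampled field grids.

#' Export a field grid to CSV or legacy VTK
#'
#' CSV files use full-precision decimal serialisation (17 significant
#' digits), so a re-read reproduces the values bit-exactly.  VTK output is
#' a legacy-format ASCII `STRUCTURED_POINTS` dataset with one scalar array
#' per grid column, suitable for ParaView.
#'
#' @param grid a `"field_grid"` from [field_grid()].
#' @param path output file path.
#' @param format `"csv"` or `"vtk"`.
#' @return `path`, invisibly.
#' @export
export_grid <- function(grid, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  if (!inherits(grid, "field_grid") || nrow(grid) == 0)
    stop("empty or invalid field grid")
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  ok <- tryCatch({
    if (format == "csv") {
      df <- as.data.frame(lapply(grid, function(col)
        if (is.numeric(col)) sprintf("%.17g", col) else col))
      names(df) <- names(grid)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
      geo <- attr(grid, "geometry")
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("# vtk DataFile Version 3.0",
                   "depfield field grid", "ASCII",
                   "DATASET STRUCTURED_POINTS",
                   sprintf("DIMENSIONS %d %d 1", nx, ny),
                   "ORIGIN 0 0 0",
                   sprintf("SPACING %.17g %.17g 1",
                           geo$L / (nx - 1), geo$H / (ny - 1)),
                   sprintf("POINT_DATA %d", nx * ny)), con)
      for (nm in setdiff(names(grid), c("x_star", "y_star"))) {
        v <- grid[[nm]]
        v[!is.finite(v)] <- 0
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default",
                     sprintf("%.17g", v)), con)
      }
    }
    TRUE
  }, error = function(e)
    stop("export to ", path, " failed: ", conditionMessage(e)))
  invisible(path)
}

#' Re-read an exported CSV field grid
#'
#' @param path CSV file written by [export_grid()].
#' @return data frame with the original numeric columns.
#' @export
read_grid_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
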