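# Delimited-text round trip for per-cell and per-islet feature tables.
# Numeric columns are written with 17 significant digits so double-precision
# values survive the text round trip exactly.

cellTableCoreColumns <- c(
  "cell_id", "y", "x",
  "nucleus_area_px", "nucleus_area_um2", "aspect_ratio", "circularity",
  "equivalent_radius_px", "equivalent_radius_um",
  "cell_area_px", "cell_area_um2"
)

isletTableCoreColumns <- c(
  "islet_id", "area_px", "area_um2", "aspect_ratio", "circularity", "solidity"
)

writeTableFull <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      # keep whole-valued doubles typed as doubles on re-read
      plain <- !grepl("[.eE]", v) & is.finite(out[[j]])
      v[plain] <- paste0(v[plain], ".0")
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Write / read a per-cell feature table
#'
#' Plain CSV with header; doubles are serialised with enough digits for an
#' exact round trip. `readCellTable()` validates that the core feature
#' columns are present.
#'
#' @param table data.frame as produced by [extractFeatures()].
#' @param path CSV file path.
#' @return `writeCellTable` returns `path` invisibly; `readCellTable`
#'   returns the table as a data.frame.
#' @export
writeCellTable <- function(table, path) {
  missing <- setdiff(cellTableCoreColumns, names(table))
  if (length(missing))
    stop("cell table lacks required columns: ", paste(missing, collapse = ", "))
  writeTableFull(table, path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cellTableCoreColumns, names(df))
  if (length(missing))
    stop("not a cell feature table; missing columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Write / read a per-islet feature table
#'
#' @param table data.frame as produced by [isletFeatures()].
#' @param path CSV file path.
#' @return `writeIsletTable` returns `path` invisibly; `readIsletTable`
#'   returns the table as a data.frame.
#' @export
writeIsletTable <- function(table, path) {
  missing <- setdiff(isletTableCoreColumns, names(table))
  if (length(missing))
    stop("islet table lacks required columns: ", paste(missing, collapse = ", "))
  writeTableFull(table, path)
}

#' @rdname writeIsletTable
#' @export
readIsletTable <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(isletTableCoreColumns, names(df))
  if (length(missing))
    stop("not an islet feature table; missing columns: ",
         paste(missing, collapse = ", "))
  df
}
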