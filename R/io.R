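#' Write per-nucleus records as TSV
#'
#' The package's interchange format: tab-delimited, UTF-8, mandatory header,
#' columns `nucleus_id`, `depth_x_um`, `diameter_um`, `volume_fraction`,
#' `image_fraction`, `enumerated`, `n_target`, `n_control`. Numbers are
#' serialized at full precision (15 significant digits) so a re-read
#' round-trips, and output is byte-identical for identical inputs.
#'
#' @param records Data.frame from [simulate_section()] (or compatible).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nucleus_tsv <- function(records, path) {
  cols <- c("nucleus_id", "depth_x_um", "diameter_um", "volume_fraction",
            "image_fraction", "enumerated", "n_target", "n_control")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("records missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- records[cols]
  for (nm in c("depth_x_um", "diameter_um", "volume_fraction",
               "image_fraction")) {
    out[[nm]] <- formatC(out[[nm]], format = "g", digits = 15)
  }
  out$enumerated <- ifelse(records$enumerated, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-nucleus TSV records
#'
#' @param path File written by [write_nucleus_tsv()] or any per-nucleus
#'   count table with the same schema.
#' @return Data.frame with the interchange columns, types restored.
#' @export
read_nucleus_tsv <- function(path) {
  rec <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#", fileEncoding = "UTF-8")
  if (!"nucleus_id" %in% names(rec)) {
    stop("not a per-nucleus TSV: missing header", call. = FALSE)
  }
  rec$enumerated <- as.logical(rec$enumerated)
  rec
}

#' Locate a packaged demo table
#'
#' Three demo CSVs transcribe published per-slide FISH scoring summaries
#' (mean copy numbers and coefficients of variation at several section
#' thicknesses): `her2_breast_cases.csv` (four breast-carcinoma cases),
#' `her2_cellline_controls.csv` (negative and positive cell-line controls),
#' `met_lung_case.csv` (one lung-cancer case, MET/CEP7). They are inputs for
#' demonstration of classification and correction only; the package never
#' recomputes them.
#'
#' @param name One of the file names above, or `NULL` to list them.
#' @return Full path (or a vector of available names).
#' @export
demo_table <- function(name = NULL) {
  dir <- system.file("extdata", package = "fishsect")
  if (is.null(name)) return(list.files(dir, pattern = "\\.csv$"))
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no such demo table: ", name, call. = FALSE)
  path
}
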