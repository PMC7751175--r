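#' @keywords internal
assay_columns <- c("isoform_id", "run_id", "replicate_id", "pep_uM",
                   "hco3_uM", "inhibitor", "inhibitor_mM", "enzyme_nM",
                   "rate_uM_per_s", "is_blank")

#' Validate an assay-point table
#'
#' An assay-point table holds one row per measured well, with nominal
#' substrate concentrations, inhibitor identity and concentration (mM at
#' the interface), total enzyme concentration (nM), run and replicate
#' labels, the blank-corrected initial rate (uM/s) and a flag for
#' no-enzyme blank wells. Blank-corrected rates may be slightly negative;
#' they are retained, not clipped.
#'
#' @param points A data.frame with columns \code{isoform_id, run_id,
#'   replicate_id, pep_uM, hco3_uM, inhibitor, inhibitor_mM, enzyme_nM,
#'   rate_uM_per_s, is_blank}.
#' @return The validated data.frame, invisibly coerced (run ids as
#'   character, \code{is_blank} as logical).
#' @export
validate_assay_points <- function(points) {
  stopifnot(is.data.frame(points))
  missing_cols <- setdiff(assay_columns, names(points))
  if (length(missing_cols)) {
    stop("assay table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  points$run_id <- as.character(points$run_id)
  points$replicate_id <- as.character(points$replicate_id)
  points$isoform_id <- as.character(points$isoform_id)
  points$inhibitor <- as.character(points$inhibitor)
  points$is_blank <- as.logical(points$is_blank)
  num <- c("pep_uM", "hco3_uM", "inhibitor_mM", "enzyme_nM", "rate_uM_per_s")
  for (col in num) points[[col]] <- as.numeric(points[[col]])
  if (any(points$pep_uM < 0) || any(points$hco3_uM < 0) ||
      any(points$inhibitor_mM < 0) || any(points$enzyme_nM < 0)) {
    stop("concentrations must be non-negative")
  }
  if (any(!nzchar(points$run_id))) stop("run_id must be nonempty")
  points
}

#' Read an assay-point table from delimited text
#'
#' @param path Path to a comma- or tab-delimited file with a header row
#'   and the columns listed in \code{\link{validate_assay_points}}.
#' @param sep Field separator; guessed from the first line when NULL.
#' @return A validated assay-point data.frame.
#' @export
read_assay_points <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  validate_assay_points(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  )
}

#' Write an assay-point table as delimited text
#'
#' @param points Assay-point data.frame.
#' @param path Output path.
#' @param sep Field separator, default tab.
#' @export
write_assay_points <- function(points, path, sep = "\t") {
  points <- validate_assay_points(points)
  utils::write.table(points[, assay_columns], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
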