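#' Read a labeled expression matrix from delimited text
#'
#' Reads a TSV/CSV expression table into an [ExpressionDataset-class].
#' With `orientation = "samples"` rows are samples, columns are genes, the
#' first column holds sample identifiers and one reserved column (named by
#' `labelField`) holds the class labels. With `orientation = "genes"` rows
#' are genes (first column gene identifiers), columns are samples, and one
#' reserved row (named by `labelField`) holds the labels.
#'
#' Class labels are normalized to \{-1, +1\}: numeric \{0, 1\} map to
#' \{-1, +1\}, and the case-insensitive strings "normal" -> -1 and
#' "cancer"/"tumor"/"tumour" -> +1 are accepted. Any other label value is
#' an error.
#'
#' Missing or non-numeric expression cells are rejected by default. With
#' `missing = "uniform"` each invalid cell is replaced by a fresh draw
#' from Uniform(0, 1) — regenerated on every load, so repeated loads of
#' a file with invalid entries differ in those cells.
#'
#' @param path file to read.
#' @param orientation `"samples"` (samples in rows, default) or `"genes"`.
#' @param labelField name of the label column/row (default `"label"`).
#' @param sep field separator; default inferred from the file extension
#'   (`","` for `.csv`, tab otherwise).
#' @param missing `"error"` (default) or `"uniform"` (substitute each
#'   invalid cell with a Uniform(0,1) draw).
#'
#' @return An [ExpressionDataset-class]. A warning (not an error) is
#'   issued when only one class is present, since single-class sets are
#'   legitimate as validation-only inputs.
#' @seealso [writeExpressionDataset()]
#' @export
readExpressionDataset <- function(path,
                                  orientation = c("samples", "genes"),
                                  labelField = "label",
                                  sep = NULL,
                                  missing = c("error", "uniform")) {
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (orientation == "genes") {
    if (!labelField %in% rownames(raw))
      stop("label row '", labelField, "' not found in ", path)
    labRaw <- as.character(raw[labelField, ])
    mat <- t(as.matrix(raw[setdiff(rownames(raw), labelField), , drop = FALSE]))
  } else {
    if (!labelField %in% colnames(raw))
      stop("label column '", labelField, "' not found in ", path)
    labRaw <- as.character(raw[[labelField]])
    mat <- as.matrix(raw[, setdiff(colnames(raw), labelField), drop = FALSE])
  }
  labels <- normalizeLabels(labRaw)
  vals <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat),
                                  dimnames = dimnames(mat)))
  bad <- !is.finite(vals)
  if (any(bad)) {
    if (missing == "error") {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop("non-numeric or missing expression value '", mat[bad][1],
           "' at sample '", rownames(mat)[idx[1]], "', gene '",
           colnames(mat)[idx[2]], "'")
    }
    vals[bad] <- stats::runif(sum(bad))
  }
  if (anyDuplicated(colnames(vals)))
    stop("duplicate gene identifier: ",
         colnames(vals)[duplicated(colnames(vals))][1])
  if (length(unique(labels)) < 2)
    warning("dataset contains a single class; a classifier cannot be fit on it")
  ExpressionDataset(vals, labels,
                    geneIds = colnames(vals), sampleIds = rownames(vals))
}

## {-1,+1} kept; {0,1} -> {-1,+1}; normal -> -1, cancer/tumor -> +1
normalizeLabels <- function(x) {
  out <- rep(NA_real_, length(x))
  lx <- tolower(trimws(x))
  out[lx %in% c("-1")] <- -1
  out[lx %in% c("1", "+1")] <- 1
  out[lx %in% c("0")] <- -1
  out[lx %in% c("normal")] <- -1
  out[lx %in% c("cancer", "tumor", "tumour")] <- 1
  # "1" above maps to +1 under both encodings, so only genuinely unknown
  # values remain NA
  if (anyNA(out))
    stop("unrecognized class label value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected -1/+1, 0/1, or normal/cancer)")
  out
}

#' Write an ExpressionDataset as delimited text
#'
#' Writes samples in rows with a first `sample` identifier column, gene
#' identifiers as remaining column names, and the labels in a reserved
#' column. Values are written with 15 significant digits so that a
#' write/read round trip is value-exact.
#'
#' @param ds an [ExpressionDataset-class].
#' @param path output file; `.csv` extension selects comma separation,
#'   anything else tab.
#' @param labelField name for the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
writeExpressionDataset <- function(ds, path, labelField = "label") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample = sampleIds(ds),
                   format(unname(ds@values), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample", geneIds(ds))
  df[[labelField]] <- classLabels(ds)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write extraction reports
#'
#' Writes the results of a feature extraction run to a directory:
#' \describe{
#'   \item{`selected_genes.txt`}{one selected gene identifier per line, in
#'     rank order;}
#'   \item{`margin_curve.tsv`}{columns `i`, `W` — the error-margin curve;}
#'   \item{`breakpoint_errors.tsv`}{columns `f`, `epsilon` — the residual
#'     profile of the segmented fits over candidate breakpoints;}
#'   \item{`summary.json`}{f0, the selected identifiers, and run
#'     parameters.}
#' }
#'
#' @param fs a [FeatureSet-class].
#' @param curve the [MarginCurve-class] the selection was based on.
#' @param fits data.frame with columns `f` and `epsilon` (as returned in
#'   `$profile` by [findCriticalPoint()]).
#' @param path output directory (created if needed).
#' @param parameters named list recorded verbatim in the summary.
#' @return The directory path, invisibly.
#' @export
writeReport <- function(fs, curve, fits, path, parameters = list()) {
  stopifnot(is.data.frame(fits), all(c("f", "epsilon") %in% names(fits)))
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE)
  writeLines(geneIds(fs), file.path(path, "selected_genes.txt"))
  utils::write.table(
    data.frame(i = seq_along(curveValues(curve)), W = curveValues(curve)),
    file.path(path, "margin_curve.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fits[, c("f", "epsilon")],
    file.path(path, "breakpoint_errors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    f0 = featureSize(fs),
    selected = geneIds(fs),
    rank = seq_len(featureSize(fs)),
    parameters = parameters
  )
  jsonlite::write_json(summary, file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
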