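#' Read a samples-by-features matrix from delimited text
#'
#' Expects a header row of feature IDs and a first column of sample IDs.
#' Parsing is strict: every cell must be numeric, sample IDs must be unique,
#' and missing cells are an error unless median imputation is requested.
#'
#' @param path file path to a TSV/CSV matrix.
#' @param sep field delimiter; \code{NULL} guesses from the file extension
#'   (".csv" means comma, anything else tab).
#' @param impute \code{"none"} (default) rejects missing values;
#'   \code{"median"} replaces each missing cell by its feature's column
#'   median over the observed samples.
#' @return numeric matrix with sample IDs as rownames and feature IDs as
#'   colnames.
#' @export
loadFeatureMatrix <- function(path, sep = NULL, impute = c("none", "median")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", row.names = NULL,
                   stringsAsFactors = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  X <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    cell <- trimws(vals[, j])
    empty <- is.na(cell) | cell == "" | toupper(cell) == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1L]], colnames(vals)[j], cell[bad[1L]]))
    num[empty] <- NA_real_
    X[, j] <- num
  }
  if (anyNA(X)) {
    if (impute == "none") {
      miss <- which(is.na(X), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at row '%s', column '%s' (use impute = 'median')",
                   rownames(X)[miss[1L]], colnames(X)[miss[2L]]))
    }
    for (j in which(colSums(is.na(X)) > 0L)) {
      med <- median(X[, j], na.rm = TRUE)
      if (is.na(med)) stop("column '", colnames(X)[j], "' entirely missing")
      X[is.na(X[, j]), j] <- med
    }
  }
  if (nrow(X) < 2L) stop("need at least 2 samples")
  X
}

#' Write a feature matrix as delimited text
#'
#' Inverse of \code{\link{loadFeatureMatrix}}; \code{format(..., digits = 17)}
#' keeps decimal-representable values round-trip exact.
#'
#' @param X numeric matrix with sample rownames and feature colnames.
#' @param path output path.
#' @param sep field delimiter.
#' @export
writeFeatureMatrix <- function(X, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(X),
                   format(X, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(X))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read a label file (sample_id, label in \{-1, +1\})
#'
#' @param path TSV/CSV with two columns: sample ID and label.
#' @param sep delimiter; guessed from the extension when \code{NULL}.
#' @return named numeric vector of labels in study order.
#' @export
readLabels <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE)
  y <- as.numeric(df[[2L]])
  if (!all(y %in% c(-1, 1)))
    stop("labels on disk must be -1 or +1")
  if (anyDuplicated(df[[1L]])) stop("duplicate sample id in labels")
  setNames(y, as.character(df[[1L]]))
}

#' Read a cluster/family assignment file (sample_id, cluster_id)
#'
#' @inheritParams readLabels
#' @return named character vector of cluster IDs.
#' @export
readClusters <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]])) stop("duplicate sample id in clusters")
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a PredictionResult as TSV
#'
#' Columns: sample_id, predicted_label, score, score_kind.
#'
#' @param pred a \code{PredictionResult}.
#' @param path output path.
#' @export
writePredictions <- function(pred, path) {
  ids <- pred@sampleIds
  if (!length(ids)) ids <- as.character(seq_along(pred@predicted))
  df <- data.frame(sample_id = ids, predicted_label = pred@predicted,
                   score = pred@scores, score_kind = pred@scoreKind)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Export a weight matrix as a three-column edge list
#'
#' Writes one row (i, j, weight) per nonzero entry of the upper triangle
#' (symmetric matrices) or of the full off-diagonal (asymmetric).
#'
#' @param W numeric weight matrix.
#' @param path output path.
#' @param symmetric write only the upper triangle.
#' @export
writeEdgeList <- function(W, path, symmetric = TRUE) {
  idx <- which(if (symmetric) upper.tri(W) & W != 0 else
                 W != 0 & row(W) != col(W), arr.ind = TRUE)
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  df <- data.frame(i = ids[idx[, 1L]], j = ids[idx[, 2L]],
                   weight = W[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
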