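#' Construct a MultiOmicsStudy from already-aligned pieces
#'
#' @param sources named list of numeric matrices (samples x features), all
#'   with identical rownames in identical order.
#' @param labels named numeric vector in \{-1, 0, +1\}; its order is the
#'   canonical study order.
#' @param clusters optional named character vector of cluster/family IDs.
#' @return a validated \code{MultiOmicsStudy}.
#' @export
MultiOmicsStudy <- function(sources, labels, clusters = NULL) {
  if (is.null(names(sources)) || any(names(sources) == ""))
    names(sources) <- paste0("source", seq_along(sources))
  cl <- if (is.null(clusters)) character() else
    as.character(clusters)[match(names(labels), names(clusters))]
  new("MultiOmicsStudy", sources = sources,
      labels = setNames(as.numeric(labels), names(labels)),
      clusters = unname(cl))
}

#' Align data sources and labels to their common samples
#'
#' Restricts every source to the sample IDs present in all sources and in
#' the label file, reordering rows to the label-file order (the canonical
#' study order). Dropped IDs are reported via \code{message}.
#'
#' @param sources named list of numeric matrices with sample rownames.
#' @param labels named numeric vector in \{-1, 0, +1\}.
#' @param clusters optional named character vector of cluster IDs.
#' @return a \code{MultiOmicsStudy} over the common samples.
#' @export
alignStudy <- function(sources, labels, clusters = NULL) {
  if (is.null(names(sources)) || any(names(sources) == ""))
    names(sources) <- paste0("source", seq_along(sources))
  common <- names(labels)
  for (X in sources) common <- intersect(common, rownames(X))
  if (length(common) == 0L)
    stop("empty sample-id intersection across sources and labels")
  keep <- names(labels)[names(labels) %in% common]  # labels order canonical
  dropped <- setdiff(unique(c(names(labels),
                              unlist(lapply(sources, rownames)))), keep)
  if (length(dropped))
    message("alignStudy: dropped ", length(dropped), " sample(s): ",
            paste(head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  y <- labels[keep]
  if (all(y == 0)) stop("all labels are 0 after alignment")
  src <- lapply(sources, function(X) X[keep, , drop = FALSE])
  cl <- if (is.null(clusters)) NULL else clusters[keep]
  MultiOmicsStudy(src, y, cl)
}

#' Standardize features to zero mean and unit standard deviation
#'
#' Each column is centered and scaled by its sample standard deviation
#' (denominator n - 1). Zero-variance columns cannot be scaled and are
#' dropped with a warning.
#'
#' @param X numeric matrix (samples x features).
#' @return the standardized matrix, possibly with fewer columns.
#' @export
zscoreFeatures <- function(X) {
  s <- apply(X, 2L, sd)
  zero <- !is.finite(s) | s < .Machine$double.eps
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance feature(s)")
    X <- X[, !zero, drop = FALSE]
    s <- s[!zero]
  }
  scale(X, center = TRUE, scale = s)[, , drop = FALSE]
}

#' Standardize every source of a study
#'
#' @param study a \code{MultiOmicsStudy}.
#' @return the study with each source passed through
#'   \code{\link{zscoreFeatures}}.
#' @export
zscoreStudy <- function(study) {
  study@sources <- lapply(study@sources, zscoreFeatures)
  validObject(study)
  study
}

# Blind a set of samples: transductive methods see their labels as 0.
blindLabels <- function(y, testIdx) {
  y[testIdx] <- 0
  y
}
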