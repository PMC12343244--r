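# Dataset loading and preparation: molecules are parsed and decomposed once,
# and the cached graphs/motif graphs are reused by every training epoch.

#' Read a molecule CSV
#'
#' Expects a SMILES column plus one or more target columns; blank cells in
#' target columns become NA and are masked out of the training loss
#' (standard multi-task practice).
#'
#' @param path CSV file path.
#' @param smilesCol name of the SMILES column.
#' @param targetCols names of target columns; all remaining columns when
#'   NULL.
#' @return list with \code{smiles} and a numeric \code{labels} matrix.
#' @export
readMoleculeCSV <- function(path, smilesCol = "smiles", targetCols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!smilesCol %in% names(df))
    stop("no column '", smilesCol, "' in ", path)
  if (is.null(targetCols)) targetCols <- setdiff(names(df), smilesCol)
  if (length(targetCols) == 0L) stop("no target columns in ", path)
  labels <- as.matrix(df[, targetCols, drop = FALSE])
  storage.mode(labels) <- "double"
  list(smiles = df[[smilesCol]], labels = labels)
}

#' Prepare a dataset for training and evaluation
#'
#' Parses every SMILES, decomposes it and builds its motif graph against
#' the supplied vocabulary; the expensive chemistry runs once up front.
#' Unparseable molecules are dropped with their error recorded.
#'
#' @param smiles character vector of SMILES.
#' @param labels numeric vector or matrix of targets (one row per molecule),
#'   or NULL for unlabeled data.
#' @param vocab a [MotifVocabulary-class].
#' @return list with \code{entries} (cached graph + motif graph per
#'   molecule), \code{smiles} (canonical), \code{labels} (numeric matrix)
#'   and \code{failures} (data.frame of dropped inputs).
#' @export
prepareDataset <- function(smiles, labels = NULL, vocab) {
  if (!is.null(labels)) {
    if (is.data.frame(labels)) labels <- as.matrix(labels)
    if (!is.matrix(labels)) labels <- matrix(labels, ncol = 1L)
    if (nrow(labels) != length(smiles))
      stop("labels and smiles lengths differ")
  }
  entries <- vector("list", length(smiles))
  ok <- logical(length(smiles))
  errs <- character(0); badSmi <- character(0)
  for (i in seq_along(smiles)) {
    res <- tryCatch(.prepareEntry(smiles[i], vocab), error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, conditionMessage(res))
      badSmi <- c(badSmi, smiles[i])
    } else {
      entries[[i]] <- res
      ok[i] <- TRUE
    }
  }
  list(entries = entries[ok],
       smiles = vapply(entries[ok], function(e) e$graph@smiles, character(1)),
       labels = if (is.null(labels)) NULL else labels[ok, , drop = FALSE],
       failures = data.frame(smiles = badSmi, error = errs,
                             stringsAsFactors = FALSE))
}
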