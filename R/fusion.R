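# Dual-granularity fusion: atomic embeddings are projected onto motifs via
# the association matrix and added to the motifs' identity embeddings; the
# [GLOBAL] node keeps its own embedding and is reintroduced as the last row.

#' Project atomic features onto motifs
#'
#' Computes \code{ReLU((1/m) F X W + b)}: the association matrix sums the
#' atom embeddings of each motif, the \code{1/m} factor (total atom count)
#' normalizes against size bias, and a learnable linear map aligns the
#' result with the motif embedding width. With \code{perMotif = TRUE} the
#' normalization uses each motif's own atom count (row sums of \code{F})
#' instead of the molecule total.
#'
#' @param F binary motif-by-atom association matrix (columns sum to 1).
#' @param X atom embedding matrix (atoms x hidden).
#' @param W,b learnable projection weight (hidden x out) and bias (length
#'   out).
#' @param m total atom count used for normalization; defaults to
#'   \code{nrow(X)}.
#' @param perMotif normalize by per-motif atom counts instead of \code{m}.
#' @return motif-by-out matrix of projected atomic features.
#' @examples
#' F <- matrix(c(1, 1), 1)          # one motif holding two atoms
#' X <- rbind(c(1, 0), c(3, 2))
#' projectAtomsToMotifs(F, X, diag(2), c(0, 0))   # (1+3)/2, (0+2)/2
#' @export
projectAtomsToMotifs <- function(F, X, W, b, m = nrow(X), perMotif = FALSE) {
  if (ncol(F) != nrow(X))
    stop("association matrix and atom embeddings disagree on atom count")
  agg <- F %*% X
  norm <- if (perMotif) pmax(rowSums(F), 1) else m
  .reluM((agg / norm) %*% W + rep(b, each = nrow(F)))
}

#' Fuse projected atomic features with motif identity embeddings
#'
#' Element-wise addition of the structural (atom-derived) and categorical
#' (vocabulary embedding) views of each motif; the \code{[GLOBAL]} node,
#' set aside during fusion, is reintroduced as the final row carrying its
#' embedding alone.
#'
#' @param projected motif-by-d matrix from [projectAtomsToMotifs()].
#' @param identityEmbeddings motif-by-d matrix of identity embeddings.
#' @param globalEmbedding length-d embedding of the \code{[GLOBAL]} node.
#' @return (motifs + 1) x d fused feature matrix, global row last.
#' @export
fuseMotifFeatures <- function(projected, identityEmbeddings, globalEmbedding) {
  if (!identical(dim(projected), dim(identityEmbeddings)))
    stop("projected and identity embedding shapes differ")
  if (length(globalEmbedding) != ncol(projected))
    stop("global embedding width differs from motif features")
  rbind(projected + identityEmbeddings, matrix(globalEmbedding, 1L))
}
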