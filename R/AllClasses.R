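#' @import methods
NULL

#' Directed molecular graph with atom and bond feature vectors
#'
#' A molecule parsed from SMILES, stored as a directed graph: every chemical
#' bond contributes two directed edges (one per direction) carrying identical
#' bond feature vectors. Atom order follows the toolkit's canonical SMILES
#' atom order, so two SMILES spellings of the same molecule yield identical
#' objects. Hydrogens are implicit (heavy atoms only).
#'
#' @slot smiles canonical SMILES the graph was built from.
#' @slot atomFeatures numeric matrix, one row per atom (fixed width
#'   \code{atomFeatureLength()}).
#' @slot bondFeatures numeric matrix, one row per directed edge (fixed width
#'   \code{bondFeatureLength()}).
#' @slot edges integer matrix with columns \code{src}, \code{dst}, one row per
#'   directed edge.
#' @slot reverseIndex integer vector mapping each directed edge to its reverse
#'   partner (an involution with no fixed points).
#' @slot elements element symbol per atom.
#' @slot aromaticAtom logical aromaticity flag per atom.
#' @slot formalCharge integer formal charge per atom.
#' @slot numH implicit hydrogen count per atom.
#' @slot bondOrder numeric bond order per directed edge (1, 2, 3; aromatic
#'   ring bonds keep their kekulized order and are flagged via
#'   \code{aromaticBond}).
#' @slot aromaticBond logical per directed edge.
#' @slot ringBond logical per directed edge.
#'
#' @seealso [smilesToGraph()]
#' @export
setClass("MolecularGraph",
  representation(
    smiles = "character",
    atomFeatures = "matrix",
    bondFeatures = "matrix",
    edges = "matrix",
    reverseIndex = "integer",
    elements = "character",
    aromaticAtom = "logical",
    formalCharge = "integer",
    numH = "integer",
    bondOrder = "numeric",
    aromaticBond = "logical",
    ringBond = "logical"
  )
)

setValidity("MolecularGraph", function(object) {
  m <- nrow(object@atomFeatures)
  ne <- nrow(object@edges)
  msgs <- character()
  if (nrow(object@bondFeatures) != ne)
    msgs <- c(msgs, "bondFeatures row count must equal directed edge count")
  if (length(object@reverseIndex) != ne)
    msgs <- c(msgs, "reverseIndex length must equal directed edge count")
  if (ne > 0) {
    if (any(object@edges < 1L) || any(object@edges > m))
      msgs <- c(msgs, "edge indices out of range")
    rev <- object@reverseIndex
    if (any(rev[rev] != seq_len(ne)))
      msgs <- c(msgs, "reverseIndex must be an involution")
    if (any(rev == seq_len(ne)))
      msgs <- c(msgs, "reverseIndex must have no fixed points")
    if (any(object@edges[rev, 1L] != object@edges[, 2L]))
      msgs <- c(msgs, "reverse edge must swap source and target")
    if (any(abs(object@bondFeatures - object@bondFeatures[rev, , drop = FALSE]) > 0))
      msgs <- c(msgs, "both directions of a bond must carry identical features")
  }
  if (length(object@elements) != m)
    msgs <- c(msgs, "elements length must equal atom count")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MolecularGraph number of atoms
#' @param x,object a \code{MolecularGraph}
#' @export
setMethod("length", "MolecularGraph", function(x) nrow(x@atomFeatures))

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph:", object@smiles, "\n")
  cat(" ", nrow(object@atomFeatures), "atoms,",
      nrow(object@edges), "directed edges (",
      nrow(object@edges) / 2L, "bonds )\n")
})

#' Number of atoms in a molecular graph
#' @param graph a \code{MolecularGraph}
#' @return integer atom count
#' @export
numAtoms <- function(graph) nrow(graph@atomFeatures)

#' Directed edge list of a molecular graph
#' @param graph a \code{MolecularGraph}
#' @return integer matrix with columns src, dst
#' @export
edgeList <- function(graph) graph@edges

#' Atom feature matrix accessor
#' @param graph a \code{MolecularGraph}
#' @return numeric matrix, one row per atom
#' @export
atomFeatures <- function(graph) graph@atomFeatures

#' Bond feature matrix accessor (per directed edge)
#' @param graph a \code{MolecularGraph}
#' @return numeric matrix, one row per directed edge
#' @export
bondFeatures <- function(graph) graph@bondFeatures

#' Motif vocabulary
#'
#' Bijection between canonical motif keys (canonical SMILES of fragments) and
#' integer indices \code{1..L-1}, with the last index \code{L} reserved for
#' the \code{[UNK]} token covering motifs unseen at build time. Keys are
#' stored lexicographically sorted so indices are reproducible regardless of
#' corpus order.
#'
#' @slot keys sorted character vector of observed motif keys.
#' @seealso [buildMotifVocabulary()], [motifIndex()]
#' @export
setClass("MotifVocabulary", representation(keys = "character"))

setValidity("MotifVocabulary", function(object) {
  if (anyDuplicated(object@keys)) return("motif keys must be unique")
  if (!identical(object@keys, sort(object@keys, method = "radix")))
    return("motif keys must be sorted (C collation)")
  TRUE
})

setMethod("show", "MotifVocabulary", function(object) {
  cat("MotifVocabulary:", length(object@keys),
      "observed motifs + [UNK] (L =", vocabSize(object), ")\n")
})

#' Vocabulary size including the reserved [UNK] index
#' @param vocab a \code{MotifVocabulary}
#' @return integer L
#' @export
vocabSize <- function(vocab) length(vocab@keys) + 1L

#' Index of the reserved [UNK] token
#' @param vocab a \code{MotifVocabulary}
#' @return integer
#' @export
unkIndex <- function(vocab) length(vocab@keys) + 1L

#' Look up vocabulary indices for motif keys
#'
#' Unknown keys map to the reserved \code{[UNK]} index.
#' @param vocab a \code{MotifVocabulary}
#' @param keys character vector of motif keys
#' @return integer vector of indices in \code{1..vocabSize(vocab)}
#' @export
motifIndex <- function(vocab, keys) {
  idx <- match(keys, vocab@keys)
  idx[is.na(idx)] <- unkIndex(vocab)
  idx
}

#' Motif-level graph with auxiliary matrices
#'
#' The motif graph of one molecule: one node per fragment plus an appended
#' \code{[GLOBAL]} node. \code{A} is the binary motif adjacency (motifs are
#' adjacent iff an original bond crosses their fragments; the \code{[GLOBAL]}
#' node is adjacent to every motif), \code{D} holds shortest-path hop counts
#' with the \code{[GLOBAL]} row/column fixed to 1, and \code{F} is the binary
#' motif-by-atom association matrix (special nodes excluded; columns sum to 1
#' because fragments partition the atoms).
#'
#' @slot n motif count excluding the special node.
#' @slot motifKeys canonical key per motif.
#' @slot motifIndices vocabulary index per motif ([UNK] where unseen).
#' @slot onehots n x L binary matrix of motif one-hots.
#' @slot A (n+1) x (n+1) binary adjacency, global node last.
#' @slot D (n+1) x (n+1) nonnegative integer distance matrix.
#' @slot F n x m binary motif-atom association matrix.
#' @slot globalIndex row/column of the [GLOBAL] node (always n+1).
#' @slot atomIndices list of atom index vectors, one per motif.
#' @seealso [buildMotifGraph()], [decomposeMotifs()]
#' @export
setClass("MotifGraph",
  representation(
    n = "integer",
    motifKeys = "character",
    motifIndices = "integer",
    onehots = "matrix",
    A = "matrix",
    D = "matrix",
    F = "matrix",
    globalIndex = "integer",
    atomIndices = "list"
  )
)

setValidity("MotifGraph", function(object) {
  n <- object@n
  msgs <- character()
  if (!identical(dim(object@A), c(n + 1L, n + 1L)))
    msgs <- c(msgs, "A must be (n+1) x (n+1)")
  if (!identical(dim(object@D), c(n + 1L, n + 1L)))
    msgs <- c(msgs, "D must be (n+1) x (n+1)")
  if (any(object@A != t(object@A))) msgs <- c(msgs, "A must be symmetric")
  if (any(diag(object@A) != 0)) msgs <- c(msgs, "A must have zero diagonal")
  if (any(object@D != t(object@D))) msgs <- c(msgs, "D must be symmetric")
  if (any(diag(object@D) != 0)) msgs <- c(msgs, "D must have zero diagonal")
  g <- object@globalIndex
  if (n > 0) {
    if (any(object@D[g, -g] != 1))
      msgs <- c(msgs, "distance from [GLOBAL] to every motif must be 1")
    if (any(rowSums(object@onehots) != 1))
      msgs <- c(msgs, "each one-hot row must sum to 1")
    if (ncol(object@F) > 0 && any(colSums(object@F) != 1))
      msgs <- c(msgs, "each atom must belong to exactly one motif")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifGraph", function(object) {
  cat("MotifGraph:", object@n, "motifs + [GLOBAL],",
      ncol(object@F), "atoms\n")
  cat("  keys:", paste(object@motifKeys, collapse = " | "), "\n")
})

#' Accessors for motif graph matrices
#'
#' @param mg a \code{MotifGraph}
#' @return the requested matrix (adjacency, distance or association).
#' @export
adjacencyMatrix <- function(mg) mg@A

#' @rdname adjacencyMatrix
#' @export
distanceMatrix <- function(mg) mg@D

#' @rdname adjacencyMatrix
#' @export
associationMatrix <- function(mg) mg@F

#' Dual-granularity molecular property model
#'
#' Holds all learnable parameters of the pipeline: the communicative
#' message-passing encoder, the motif fusion projection and identity
#' embedding table, the stacked global/local masked attention layers, the
#' learnable residual scale alpha, and the linear prediction head; plus the
#' motif vocabulary and the configuration it was built with.
#'
#' @slot params named list of numeric parameter matrices.
#' @slot config named list of configuration values (see
#'   [motifFuseConfig()]).
#' @slot vocab the \code{MotifVocabulary} the model embeds.
#' @seealso [motifFuseModel()], [trainModel()]
#' @export
setClass("MotifFuseModel",
  representation(params = "list", config = "list", vocab = "MotifVocabulary")
)

setMethod("show", "MotifFuseModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cfg <- object@config
  cat("MotifFuseModel\n")
  cat("  hidden size:", cfg$hiddenSize, " depth:", cfg$depth,
      " attention layers:", cfg$attnLayers,
      " heads/channel:", cfg$headsPerChannel, "\n")
  cat("  vocabulary: L =", vocabSize(object@vocab),
      "  targets:", cfg$nTargets, paste0("(", cfg$taskType, ")"), "\n")
  cat("  parameters:", format(np, big.mark = ","), "\n")
})
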