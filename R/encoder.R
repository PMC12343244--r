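# Communicative message passing over the directed molecular graph: nodes
# aggregate incoming edge messages (sum * elementwise max), edges are
# refreshed from the source node minus the reverse edge, and a final
# communicate step mixes node state, aggregated messages and the projected
# input features. Readout is a bidirectional gated recurrent pass over the
# canonical atom order followed by mean pooling.

.reluM <- function(x) x * (x > 0)

#' Aggregate incoming edge features into node messages
#'
#' The node message is the elementwise product of the elementwise sum and the
#' elementwise maximum of its incoming edge features, capturing both the
#' neighborhood total and its most salient component. Nodes with no incoming
#' edges get the zero vector.
#'
#' @param edgeHidden numeric matrix, one row per directed edge.
#' @param incoming list (one element per node) of incoming edge row indices.
#' @return numeric matrix with one message row per node.
#' @examples
#' e <- rbind(c(1, 0), c(0, 1))
#' aggregateIncoming(e, list(1:2))   # sum [1,1] * max [1,1] = [1,1]
#' @export
aggregateIncoming <- function(edgeHidden, incoming) {
  d <- ncol(edgeHidden)
  out <- matrix(0, length(incoming), d)
  for (v in seq_along(incoming)) {
    rows <- incoming[[v]]
    if (length(rows) == 0L) next
    sub <- edgeHidden[rows, , drop = FALSE]
    out[v, ] <- colSums(sub) * apply(sub, 2L, max)
  }
  out
}

#' Update node hidden states with aggregated messages
#'
#' Additive update: the node keeps its own representation and absorbs the
#' neighborhood message.
#'
#' @param nodeHidden numeric matrix of node states.
#' @param messages matrix of the same shape from [aggregateIncoming()].
#' @return updated node state matrix.
#' @export
updateNode <- function(nodeHidden, messages) {
  if (!identical(dim(nodeHidden), dim(messages)))
    stop("node state and message shapes differ")
  nodeHidden + messages
}

#' Update directed edge hidden states
#'
#' The edge message is the source-node state minus the reverse edge state
#' (steering the direction of information flow); the new edge state applies
#' a per-layer linear map and a rectifier on top of the initial edge state.
#'
#' @param sourceHidden matrix of source-node states, one row per edge.
#' @param reverseHidden matrix of reverse-edge states, one row per edge.
#' @param edgeInit matrix of initial (projected) edge states.
#' @param W the layer's square weight matrix.
#' @return updated edge state matrix.
#' @export
updateEdge <- function(sourceHidden, reverseHidden, edgeInit, W) {
  if (ncol(sourceHidden) != nrow(W))
    stop("hidden width does not match the weight matrix")
  .reluM((sourceHidden - reverseHidden) %*% W + edgeInit)
}

# incoming edge rows per node
.incomingLists <- function(graph) {
  m <- numAtoms(graph)
  dst <- graph@edges[, 2L]
  lapply(seq_len(m), function(v) which(dst == v))
}

.gruStep <- function(x, h, w) {
  z <- 1 / (1 + exp(-(x %*% w$Wz + h %*% w$Uz + rep(w$bz, each = nrow(x)))))
  r <- 1 / (1 + exp(-(x %*% w$Wr + h %*% w$Ur + rep(w$br, each = nrow(x)))))
  hh <- tanh(x %*% w$Wh + (r * h) %*% w$Uh + rep(w$bh, each = nrow(x)))
  (1 - z) * h + z * hh
}

.gruWeights <- function(params, dir) {
  list(Wz = params[[paste0("gru_", dir, "_Wz")]],
       Uz = params[[paste0("gru_", dir, "_Uz")]],
       bz = params[[paste0("gru_", dir, "_bz")]],
       Wr = params[[paste0("gru_", dir, "_Wr")]],
       Ur = params[[paste0("gru_", dir, "_Ur")]],
       br = params[[paste0("gru_", dir, "_br")]],
       Wh = params[[paste0("gru_", dir, "_Wh")]],
       Uh = params[[paste0("gru_", dir, "_Uh")]],
       bh = params[[paste0("gru_", dir, "_bh")]])
}

# one direction of the recurrent readout over a single molecule
.gruSequence <- function(X, w) {
  dh <- ncol(w$Uz)
  h <- matrix(0, 1L, dh)
  out <- matrix(0, nrow(X), dh)
  for (t in seq_len(nrow(X))) {
    h <- .gruStep(X[t, , drop = FALSE], h, w)
    out[t, ] <- h
  }
  out
}

#' Encode a molecule into atom and molecule embeddings
#'
#' Runs the input projections, \code{depth} rounds of communicative message
#' passing, the final communicate update, and the configured readout
#' (bidirectional gated recurrent pass over the canonical atom order with
#' mean pooling, or plain mean pooling).
#'
#' @param model a [MotifFuseModel-class].
#' @param graph a [MolecularGraph-class] with at least one atom.
#' @return list with \code{atomEmbeddings} (atoms x hidden) and
#'   \code{moleculeEmbedding} (hidden-length vector).
#' @export
encodeMolecule <- function(model, graph) {
  if (numAtoms(graph) == 0L) stop("cannot encode an empty graph")
  p <- model@params
  A0 <- graph@atomFeatures
  x <- .reluM(A0 %*% p$Watom + rep(p$batom, each = nrow(A0)))
  hv <- x
  ne <- nrow(graph@edges)
  if (ne > 0L) {
    src <- graph@edges[, 1L]
    raw <- cbind(A0[src, , drop = FALSE], graph@bondFeatures)
    e0 <- .reluM(raw %*% p$Wbond + rep(p$bbond, each = ne))
    he <- e0
    incoming <- .incomingLists(graph)
    K <- model@config$depth
    if (K > 0L) for (k in seq_len(K)) {
      mv <- aggregateIncoming(he, incoming)
      hv <- updateNode(hv, mv)
      me <- hv[src, , drop = FALSE] - he[graph@reverseIndex, , drop = FALSE]
      he <- .reluM(me %*% p[[paste0("Wk_", k)]] + e0)
    }
    mv <- aggregateIncoming(he, incoming)
  } else {
    mv <- matrix(0, nrow(hv), ncol(hv))
  }
  X <- .reluM((hv + mv + x) %*% p$Wcomm + rep(p$bcomm, each = nrow(hv)))

  if (identical(model@config$readout, "mean")) {
    M <- colMeans(X)
  } else {
    fwd <- .gruSequence(X, .gruWeights(p, "f"))
    bwdRev <- .gruSequence(X[rev(seq_len(nrow(X))), , drop = FALSE],
                           .gruWeights(p, "b"))
    bwd <- bwdRev[rev(seq_len(nrow(X))), , drop = FALSE]
    M <- colMeans(cbind(fwd, bwd))
  }
  list(atomEmbeddings = X, moleculeEmbedding = M)
}

#' Pad per-molecule atom embeddings to a common length
#'
#' Appends zero rows so every molecule's atom matrix reaches the batch
#' maximum, enabling batch-wise fusion with the motif matrices. Padding rows
#' are exactly zero and, because the association matrix only addresses real
#' atom columns, padding never changes the fused motif features.
#'
#' @param xs list of numeric matrices sharing a common width.
#' @return list with \code{features} (a B x Mmax x d array) and
#'   \code{atomCounts}.
#' @export
padBatch <- function(xs) {
  widths <- vapply(xs, ncol, integer(1))
  if (length(unique(widths)) > 1L)
    stop("all molecules must share one embedding width")
  counts <- vapply(xs, nrow, integer(1))
  mmax <- max(counts)
  arr <- array(0, dim = c(length(xs), mmax, widths[1L]))
  for (i in seq_along(xs))
    arr[i, seq_len(counts[i]), ] <- xs[[i]]
  list(features = arr, atomCounts = counts)
}
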