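# Chemistry-rule fragmentation into motifs, motif vocabulary, and the motif
# graph with its adjacency (A), shortest-path distance (D) and motif-atom
# association (F) matrices.

# one row per chemical bond (a single direction of each directed pair)
.undirectedBonds <- function(graph) {
  ne <- nrow(graph@edges)
  if (ne == 0L)
    return(list(bonds = matrix(integer(0), 0L, 2L), edgeRow = integer(0)))
  keep <- which(seq_len(ne) < graph@reverseIndex)
  list(bonds = graph@edges[keep, , drop = FALSE], edgeRow = keep)
}

# Ring systems: connected components of the ring-bond subgraph. Fused and
# spiro rings merge because they share an atom. Returns an integer vector,
# 0 for acyclic atoms, otherwise the ring-system id.
.ringSystems <- function(graph) {
  m <- numAtoms(graph)
  ub <- .undirectedBonds(graph)
  ringRows <- graph@ringBond[ub$edgeRow]
  sysOf <- integer(m)
  if (!any(ringRows)) return(sysOf)
  rb <- ub$bonds[ringRows, , drop = FALSE]
  ig <- igraph::graph_from_edgelist(rb, directed = FALSE)
  if (igraph::vcount(ig) < m) ig <- igraph::add_vertices(ig, m - igraph::vcount(ig))
  comp <- igraph::components(ig)$membership
  ringAtom <- unique(as.vector(rb))
  sysOf[ringAtom] <- comp[ringAtom]
  sysOf
}

# canonical SMILES key for the fragment induced by a set of atoms
.fragmentKey <- function(graph, atomIdx) {
  atomIdx <- sort(atomIdx)
  pos <- match(seq_len(numAtoms(graph)), atomIdx)
  ub <- .undirectedBonds(graph)
  inFrag <- !is.na(pos[ub$bonds[, 1L]]) & !is.na(pos[ub$bonds[, 2L]])
  bonds <- ub$bonds[inFrag, , drop = FALSE]
  orders <- graph@bondOrder[ub$edgeRow][inFrag]
  na <- length(atomIdx); nb <- nrow(bonds)
  lines <- c("fragment", "  MotifFuse", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  lines <- c(lines, sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    graph@elements[atomIdx]))
  if (nb > 0L)
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              pos[bonds[, 1L]], pos[bonds[, 2L]],
                              as.integer(orders)))
  chg <- graph@formalCharge[atomIdx]
  charged <- which(chg != 0L)
  if (length(charged))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(charged)),
                             paste0(sprintf("%4d%4d", charged, chg[charged]),
                                    collapse = "")))
  lines <- c(lines, "M  END", "$$$$", "")
  out <- .obConvert("SDF", "CAN", paste(lines, collapse = "\n"))
  key <- sub("[\t\n].*$", "", out)
  if (!nzchar(key))
    stop("could not canonicalize fragment of '", graph@smiles, "'")
  key
}

#' Decompose a molecule into motif fragments
#'
#' Applies the two fragmentation rules: (1) every acyclic bond incident to a
#' ring system (fused/spiro rings count as one system) is cleaved, so ring
#' systems separate from their substituents and from directly bonded ring
#' systems; (2) every acyclic atom with three or more heavy-atom neighbors
#' becomes a singleton motif, all its bonds cleaved. The broken-bond set is
#' computed first and connected components taken afterwards, so the result
#' is independent of rule application order. Fragments partition the atoms.
#'
#' @param graph a [MolecularGraph-class].
#' @return a list of fragments, each a list with \code{atomIndices} (sorted
#'   integer vector) and \code{motifKey} (canonical SMILES of the induced
#'   fragment, cleaved attachment points reduced to plain valence).
#' @examples
#' frags <- decomposeMotifs(smilesToGraph("Cc1ccccc1"))
#' vapply(frags, `[[`, character(1), "motifKey")  # ring + methyl
#' @export
decomposeMotifs <- function(graph) {
  m <- numAtoms(graph)
  ub <- .undirectedBonds(graph)
  bonds <- ub$bonds
  nb <- nrow(bonds)
  sysOf <- .ringSystems(graph)
  degree <- tabulate(as.vector(graph@edges[, 1L]), nbins = m)
  highDegAcyclic <- degree >= 3L & sysOf == 0L

  broken <- logical(nb)
  if (nb > 0L) {
    ringRow <- graph@ringBond[ub$edgeRow]
    endpointInRing <- sysOf[bonds[, 1L]] > 0L | sysOf[bonds[, 2L]] > 0L
    broken <- broken | (!ringRow & endpointInRing)
    broken <- broken | highDegAcyclic[bonds[, 1L]] | highDegAcyclic[bonds[, 2L]]
  }

  keep <- bonds[!broken, , drop = FALSE]
  if (nrow(keep) > 0L) {
    ig <- igraph::graph_from_edgelist(keep, directed = FALSE)
    if (igraph::vcount(ig) < m) ig <- igraph::add_vertices(ig, m - igraph::vcount(ig))
    membership <- igraph::components(ig)$membership
  } else {
    membership <- seq_len(m)
  }
  ids <- unique(membership[order(seq_len(m))])
  lapply(ids, function(id) {
    idx <- sort(which(membership == id))
    list(atomIndices = idx, motifKey = .fragmentKey(graph, idx))
  })
}

#' Build a motif vocabulary from a SMILES corpus
#'
#' Decomposes every parseable molecule and collects the unique motif keys,
#' sorted lexicographically so indices are reproducible regardless of corpus
#' order. Unparseable entries are skipped with a warning. The last index is
#' reserved for \code{[UNK]}.
#'
#' @param corpus character vector of SMILES.
#' @return a [MotifVocabulary-class].
#' @examples
#' vocab <- buildMotifVocabulary(c("Cc1ccccc1", "CCO"))
#' vocabSize(vocab)
#' @export
buildMotifVocabulary <- function(corpus) {
  if (length(corpus) == 0L) stop("cannot build a vocabulary from an empty corpus")
  keys <- character(0)
  nOk <- 0L
  for (smi in unique(corpus)) {
    frags <- tryCatch(decomposeMotifs(smilesToGraph(smi)), error = function(e) NULL)
    if (is.null(frags)) {
      warning("skipping unparseable SMILES '", smi, "'")
      next
    }
    nOk <- nOk + 1L
    keys <- c(keys, vapply(frags, `[[`, character(1), "motifKey"))
  }
  if (nOk == 0L) stop("no parseable SMILES in corpus")
  new("MotifVocabulary", keys = sort(unique(keys), method = "radix"))
}

#' Serialize / load a motif vocabulary
#'
#' Two-column tab-separated text: motif key and integer index, with the
#' reserved \code{[UNK]} row last. Round-trips exactly.
#'
#' @param vocab a [MotifVocabulary-class].
#' @param path file path.
#' @return \code{readMotifVocabulary} returns the reloaded vocabulary.
#' @export
writeMotifVocabulary <- function(vocab, path) {
  df <- data.frame(key = c(vocab@keys, "[UNK]"),
                   index = seq_len(vocabSize(vocab)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeMotifVocabulary
#' @export
readMotifVocabulary <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "",
                          col.names = c("key", "index"),
                          stringsAsFactors = FALSE)
  keys <- df$key[order(df$index)]
  if (keys[length(keys)] != "[UNK]")
    stop("vocabulary file missing the reserved [UNK] row")
  new("MotifVocabulary", keys = keys[-length(keys)])
}

#' All-pairs shortest-path hop counts of a motif adjacency
#'
#' Breadth-first hop distances for a symmetric binary adjacency matrix.
#' Disconnected pairs get the sentinel value \code{nrow(A) + 1} (larger than
#' any true path, finite so masks stay well defined).
#'
#' @param A symmetric binary adjacency matrix (no global node).
#' @return integer matrix of hop counts with zero diagonal.
#' @export
shortestPathMatrix <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(matrix(integer(0), 0L, 0L))
  ig <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  D <- igraph::distances(ig)
  D[is.infinite(D)] <- n + 1L
  storage.mode(D) <- "integer"
  dimnames(D) <- NULL
  D
}

#' Build the motif graph of a molecule
#'
#' Assembles the motif-level graph: one-hot identity rows (unseen motifs get
#' the \code{[UNK]} bit), the adjacency matrix \code{A} (motifs adjacent iff
#' an original bond joins their fragments; the appended \code{[GLOBAL]} node
#' is adjacent to every motif), the shortest-path distance matrix \code{D}
#' (the \code{[GLOBAL]} row/column is fixed to 1), and the motif-atom
#' association matrix \code{F} built from the fragments only.
#'
#' @param graph a [MolecularGraph-class].
#' @param fragments optional decomposition from [decomposeMotifs()]; computed
#'   when missing. Must partition the molecule's atoms.
#' @param vocab a [MotifVocabulary-class].
#' @return a [MotifGraph-class].
#' @examples
#' g <- smilesToGraph("Cc1ccccc1")
#' vocab <- buildMotifVocabulary("Cc1ccccc1")
#' mg <- buildMotifGraph(g, vocab = vocab)
#' adjacencyMatrix(mg)
#' @export
buildMotifGraph <- function(graph, fragments = NULL, vocab) {
  if (is.null(fragments)) fragments <- decomposeMotifs(graph)
  m <- numAtoms(graph)
  n <- length(fragments)
  allIdx <- sort(unlist(lapply(fragments, `[[`, "atomIndices")))
  if (any(allIdx < 1L) || any(allIdx > m))
    stop("fragment atom index outside the molecule")
  if (!identical(allIdx, seq_len(m)))
    stop("fragments must partition the molecule's atoms")

  F <- matrix(0, n, m)
  fragOf <- integer(m)
  for (i in seq_len(n)) {
    F[i, fragments[[i]]$atomIndices] <- 1
    fragOf[fragments[[i]]$atomIndices] <- i
  }

  Acore <- matrix(0L, n, n)
  ub <- .undirectedBonds(graph)
  if (nrow(ub$bonds) > 0L) {
    fu <- fragOf[ub$bonds[, 1L]]
    fv <- fragOf[ub$bonds[, 2L]]
    cross <- fu != fv
    Acore[cbind(fu[cross], fv[cross])] <- 1L
    Acore[cbind(fv[cross], fu[cross])] <- 1L
  }
  Dcore <- shortestPathMatrix(Acore)

  gi <- n + 1L
  A <- matrix(0L, gi, gi)
  A[seq_len(n), seq_len(n)] <- Acore
  A[gi, seq_len(n)] <- 1L
  A[seq_len(n), gi] <- 1L
  D <- matrix(0L, gi, gi)
  D[seq_len(n), seq_len(n)] <- Dcore
  D[gi, seq_len(n)] <- 1L
  D[seq_len(n), gi] <- 1L

  keys <- vapply(fragments, `[[`, character(1), "motifKey")
  idx <- motifIndex(vocab, keys)
  onehots <- matrix(0, n, vocabSize(vocab))
  onehots[cbind(seq_len(n), idx)] <- 1

  new("MotifGraph", n = n, motifKeys = keys, motifIndices = idx,
      onehots = onehots, A = A, D = D, F = F, globalIndex = gi,
      atomIndices = lapply(fragments, `[[`, "atomIndices"))
}

#' Export a motif graph as JSON
#'
#' Writes the motif keys, atom memberships and the A/D/F matrices as plain
#' JSON lists, for debugging and downstream tooling.
#'
#' @param mg a [MotifGraph-class].
#' @param path output file; when \code{NULL} the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
exportMotifGraph <- function(mg, path = NULL) {
  obj <- list(
    n = mg@n,
    motif_keys = mg@motifKeys,
    atom_indices = mg@atomIndices,
    A = apply(mg@A, 1L, as.integer, simplify = FALSE),
    D = apply(mg@D, 1L, as.integer, simplify = FALSE),
    F = apply(mg@F, 1L, as.integer, simplify = FALSE),
    global_index = mg@globalIndex
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
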