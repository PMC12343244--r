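# Scaffold-based dataset partitioning: molecules sharing a core framework
# (ring systems plus linkers, substituents stripped) always land in the
# same split, testing generalization to unseen chemotypes.

#' Bemis-Murcko scaffold key of a molecule
#'
#' Iteratively strips terminal atoms attached by single, non-ring bonds
#' until only ring systems and their linkers remain (exocyclic
#' double-bonded atoms stay). Acyclic molecules have no framework and use
#' their canonical SMILES as their own scaffold key.
#'
#' @param smiles a single SMILES string.
#' @return the scaffold's canonical SMILES.
#' @examples
#' murckoScaffold("CCc1ccccc1O")  # benzene ring
#' @export
murckoScaffold <- function(smiles) {
  graph <- smilesToGraph(smiles)
  m <- numAtoms(graph)
  if (!any(graph@ringBond)) return(graph@smiles)
  ub <- .undirectedBonds(graph)
  bonds <- ub$bonds
  orders <- graph@bondOrder[ub$edgeRow]
  keep <- rep(TRUE, m)
  repeat {
    active <- which(keep[bonds[, 1L]] & keep[bonds[, 2L]])
    deg <- tabulate(c(bonds[active, 1L], bonds[active, 2L]), nbins = m)
    strip <- integer(0)
    for (b in active) {
      if (orders[b] != 1) next
      u <- bonds[b, 1L]; v <- bonds[b, 2L]
      if (deg[u] == 1L) strip <- c(strip, u)
      if (deg[v] == 1L) strip <- c(strip, v)
    }
    strip <- setdiff(unique(strip), which(!keep))
    if (length(strip) == 0L) break
    keep[strip] <- FALSE
  }
  .fragmentKey(graph, which(keep))
}

#' Scaffold split of a molecule set
#'
#' Groups molecules by scaffold key, sorts the clusters by size (largest
#' first, ties by key) and assigns each cluster greedily to the split
#' currently furthest below its quota, so larger clusters are placed first
#' and no scaffold ever spans two splits. With all-singleton scaffolds and
#' ratios summing to a round count the split sizes are exact.
#'
#' @param smiles character vector of parseable SMILES.
#' @param ratios train/validation/test fractions summing to 1.
#' @param seed kept for interface stability; the assignment is fully
#'   deterministic, so re-runs with any seed reproduce the same split.
#' @return list with integer index vectors \code{train}, \code{val},
#'   \code{test} and the per-molecule \code{scaffold} keys.
#' @export
scaffoldSplit <- function(smiles, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  if (length(smiles) == 0L) stop("empty molecule list")
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  scaf <- vapply(smiles, murckoScaffold, character(1), USE.NAMES = FALSE)
  clusters <- split(seq_along(smiles), scaf)
  sizes <- lengths(clusters)
  ord <- order(-sizes, names(clusters), method = "radix")
  clusters <- clusters[ord]
  if (length(clusters) == 1L) {
    warning("all molecules share one scaffold; validation and test are empty")
    return(list(train = clusters[[1L]], val = integer(0), test = integer(0),
                scaffold = scaf))
  }
  quota <- length(smiles) * ratios
  assigned <- list(train = integer(0), val = integer(0), test = integer(0))
  filled <- c(0, 0, 0)
  for (cl in clusters) {
    s <- which.max(quota - filled)   # furthest below quota; ties -> train
    assigned[[s]] <- c(assigned[[s]], cl)
    filled[s] <- filled[s] + length(cl)
  }
  list(train = sort(assigned$train), val = sort(assigned$val),
       test = sort(assigned$test), scaffold = scaf)
}
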