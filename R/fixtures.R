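# Deterministic synthetic molecules: a small template grammar over ring
# cores and common substituents. Every generated SMILES is chemically valid
# by construction, and the grammar guarantees coverage of both
# decomposition rules (ring-substituent cleavage via any substituted core;
# branching-atom isolation via the tert-butyl substituent).

.FIXTURE_CORES <- list(
  benzene = list(tokens = c("c1", "c", "c", "c", "c", "c1"), sites = 1:6),
  pyridine = list(tokens = c("c1", "c", "c", "n", "c", "c1"),
                  sites = c(1:3, 5:6)),
  cyclohexane = list(tokens = c("C1", "C", "C", "C", "C", "C1"), sites = 1:6)
)

.FIXTURE_SUBS <- c("C", "N", "C(=O)O", "F", "Cl", "Br", "C(C)(C)C")
.FIXTURE_LINKERS <- c("", "C", "CC")

.assembleCore <- function(coreName, subPos, subs, ringDigit = "1") {
  core <- .FIXTURE_CORES[[coreName]]
  tokens <- gsub("1", ringDigit, core$tokens, fixed = TRUE)
  for (k in seq_along(subPos))
    tokens[subPos[k]] <- paste0(tokens[subPos[k]], "(", subs[k], ")")
  paste(tokens, collapse = "")
}

.sampleFixture <- function() {
  twoCores <- stats::runif(1) < 0.3
  drawCore <- function(digit) {
    cn <- sample(names(.FIXTURE_CORES), 1L)
    k <- sample(0:3, 1L, prob = c(0.2, 0.4, 0.25, 0.15))
    sites <- .FIXTURE_CORES[[cn]]$sites
    pos <- if (k > 0L) sort(sample(sites, k)) else integer(0)
    subs <- if (k > 0L) sample(.FIXTURE_SUBS, k, replace = TRUE) else
      character(0)
    .assembleCore(cn, pos, subs, digit)
  }
  if (twoCores) {
    paste0(drawCore("1"), sample(.FIXTURE_LINKERS, 1L), drawCore("2"))
  } else {
    drawCore("1")
  }
}

#' Generate deterministic synthetic molecules
#'
#' Samples molecules from a fixed template grammar (benzene, pyridine and
#' cyclohexane cores; methyl, amino, carboxyl, halogen and tert-butyl
#' substituents at 0-3 positions; an optional second core joined by a short
#' linker), canonicalizes and deduplicates. Regeneration with the same
#' \code{(n, seed)} is bit-identical, and the returned set always contains
#' at least one molecule with an acyclic atom of three or more heavy
#' neighbors (a branching-rule decomposition case).
#'
#' @param n number of distinct molecules (between 1 and the grammar's
#'   capacity limit of 20000; requests above the limit or past grammar
#'   saturation raise an error naming the limit).
#' @param seed integer seed.
#' @return character vector of n canonical SMILES.
#' @export
.FIXTURE_CAPACITY <- 20000L

generateMolecules <- function(n, seed = 0L) {
  if (n < 1L) stop("n must be at least 1")
  if (n > .FIXTURE_CAPACITY)
    stop("requested ", n, " molecules, above the template grammar ",
         "capacity limit of ", .FIXTURE_CAPACITY)
  withRNG(seed, {
    seen <- character(0)
    stale <- 0L
    while (length(seen) < n) {
      if (stale > 2000L)
        stop("template grammar saturated after ", stale,
             " draws without a new molecule: requested ", n,
             ", produced ", length(seen))
      can <- canonicalSmiles(.sampleFixture())
      if (!can %in% seen) {
        seen <- c(seen, can)
        stale <- 0L
      } else stale <- stale + 1L
    }
    hasBranch <- any(vapply(seen, function(s) {
      g <- smilesToGraph(s)
      deg <- tabulate(g@edges[, 1L], nbins = numAtoms(g))
      any(.ringSystems(g) == 0L & deg >= 3L)
    }, logical(1)))
    if (!hasBranch) {
      forced <- canonicalSmiles("CC(C)(C)c1ccccc1")
      if (!forced %in% seen) seen[n] <- forced
    }
    seen
  })
}

#' Compute structural labels for synthetic molecules
#'
#' Recipes: \code{ring_count} (regression; the cyclomatic number, i.e. the
#' number of independent rings), \code{has_nitrogen} (binary), and
#' \code{motif_weighted} (regression; amino-group count minus halogen count
#' plus seeded Gaussian noise of standard deviation \code{sigma} -- a target
#' that depends on motif identities rather than molecule size).
#'
#' @param smiles character vector of parseable SMILES.
#' @param recipe one of "ring_count", "has_nitrogen", "motif_weighted".
#' @param seed seed for the noise (motif_weighted only).
#' @param sigma noise standard deviation for motif_weighted.
#' @return numeric label vector.
#' @export
labelMolecules <- function(smiles, recipe, seed = 0L, sigma = 0.1) {
  graphs <- lapply(smiles, smilesToGraph)
  base <- switch(recipe,
    ring_count = vapply(graphs, function(g) {
      nb <- nrow(g@edges) / 2
      comp <- igraph::components(igraph::graph_from_edgelist(
        rbind(.undirectedBonds(g)$bonds, cbind(seq_len(numAtoms(g)),
                                               seq_len(numAtoms(g)))),
        directed = FALSE))$no
      nb - numAtoms(g) + comp
    }, numeric(1)),
    has_nitrogen = vapply(graphs, function(g)
      as.numeric(any(g@elements == "N")), numeric(1)),
    motif_weighted = vapply(graphs, function(g) {
      amino <- sum(g@elements == "N" & !g@aromaticAtom)
      halogen <- sum(g@elements %in% c("F", "Cl", "Br", "I"))
      amino - halogen
    }, numeric(1)),
    stop("unknown recipe '", recipe, "'"))
  if (identical(recipe, "motif_weighted") && sigma > 0)
    base <- base + withRNG(seed, stats::rnorm(length(base), 0, sigma))
  base
}

#' Generate a labeled synthetic dataset
#'
#' Convenience wrapper: [generateMolecules()] plus [labelMolecules()].
#'
#' @param n number of molecules.
#' @param seed integer seed (drives both structure sampling and label
#'   noise).
#' @param recipe label recipe, see [labelMolecules()].
#' @param sigma noise level for motif_weighted.
#' @return data.frame with columns \code{smiles} and \code{label}.
#' @export
makeFixtureDataset <- function(n, seed = 0L, recipe = "motif_weighted",
                               sigma = 0.1) {
  smiles <- generateMolecules(n, seed)
  data.frame(smiles = smiles,
             label = labelMolecules(smiles, recipe, seed = seed,
                                    sigma = sigma),
             stringsAsFactors = FALSE)
}
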