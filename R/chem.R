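# SMILES parsing and featurization. Open Babel (via ChemmineOB) does the
# chemistry: canonicalization fixes the atom order and the aromaticity model,
# and its SDF output supplies the kekulized bond table. Everything derived
# here (implicit H counts, hybridization, conjugation) uses a documented
# simplified valence model on top of that output.

.ELEMENTS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na",
  "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr",
  "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf",
  "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po",
  "At", "Rn", "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm",
  "Bk", "Cf", "Es", "Fm")

.ATOMIC_MASS <- c(1.008, 4.003, 6.941, 9.012, 10.812, 12.011, 14.007,
  15.999, 18.998, 20.18, 22.99, 24.305, 26.982, 28.086, 30.974, 32.067,
  35.453, 39.948, 39.098, 40.078, 44.956, 47.867, 50.944, 51.996, 54.938,
  55.845, 58.933, 58.693, 63.546, 65.39, 69.723, 72.61, 74.922, 78.96,
  79.904, 83.8, 85.468, 87.62, 88.906, 91.224, 92.906, 95.94, 98, 101.07,
  102.906, 106.42, 107.868, 112.412, 114.818, 118.711, 121.76, 127.6,
  126.904, 131.29, 132.905, 137.328, 138.906, 140.116, 140.908, 144.24,
  145, 150.36, 151.964, 157.25, 158.925, 162.5, 164.93, 167.26, 168.934,
  173.04, 174.967, 178.49, 180.948, 183.84, 186.207, 190.23, 192.217,
  195.078, 196.967, 200.59, 204.383, 207.2, 208.98, 209, 210, 222, 223,
  226, 227, 232.038, 231.036, 238.029, 237, 244, 243, 247, 247, 251, 252,
  257)

.DEGREE_LEVELS <- 0:5
.CHARGE_LEVELS <- c(-2L, -1L, 0L, 1L, 2L)   # plus an "other" bucket
.HYBRID_LEVELS <- c("sp", "sp2", "sp3", "other")
.NUMH_LEVELS <- 0:4
.BOND_TYPES <- c("single", "double", "triple", "aromatic")

# default valence used for implicit hydrogen counting
.VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
              Cl = 1, Br = 1, I = 1)

#' Width of the atom feature vector
#'
#' Element one-hot over the first 100 elements plus an "other" bucket, degree
#' one-hot (0-5), formal charge one-hot (-2..+2 plus other), hybridization
#' one-hot (sp/sp2/sp3/other), aromaticity flag, total-H one-hot (0-4), and
#' the atomic mass divided by 100.
#'
#' @return integer feature width
#' @export
atomFeatureLength <- function() {
  length(.ELEMENTS) + 1L + length(.DEGREE_LEVELS) +
    length(.CHARGE_LEVELS) + 1L + length(.HYBRID_LEVELS) + 1L +
    length(.NUMH_LEVELS) + 1L
}

#' Width of the bond feature vector
#'
#' Bond-type one-hot (single/double/triple/aromatic), conjugation flag,
#' in-ring flag.
#'
#' @return integer feature width
#' @export
bondFeatureLength <- function() length(.BOND_TYPES) + 2L

#' Featurize one atom
#'
#' Deterministic fixed-width encoding of an atom's chemical descriptors.
#' Elements outside the configured list fall into the "other" bucket; degree
#' or hydrogen counts outside their one-hot range leave that block all-zero.
#'
#' @param element element symbol (e.g. "C").
#' @param degree heavy-atom neighbor count.
#' @param formalCharge integer formal charge.
#' @param hybridization one of "sp", "sp2", "sp3", "other".
#' @param aromatic logical aromaticity flag.
#' @param numH implicit hydrogen count.
#' @return numeric vector of length \code{atomFeatureLength()}
#' @examples
#' v <- featurizeAtom("C", 4, 0, "sp3", FALSE, 0)
#' sum(v[1:101])  # exactly one element bit
#' @export
featurizeAtom <- function(element, degree, formalCharge, hybridization,
                          aromatic, numH) {
  el <- numeric(length(.ELEMENTS) + 1L)
  i <- match(element, .ELEMENTS)
  el[if (is.na(i)) length(el) else i] <- 1
  deg <- as.numeric(.DEGREE_LEVELS == degree)
  chg <- numeric(length(.CHARGE_LEVELS) + 1L)
  j <- match(formalCharge, .CHARGE_LEVELS)
  chg[if (is.na(j)) length(chg) else j] <- 1
  hyb <- as.numeric(.HYBRID_LEVELS == hybridization)
  if (!any(hyb > 0)) hyb[length(hyb)] <- 1
  hs <- as.numeric(.NUMH_LEVELS == numH)
  mass <- .ATOMIC_MASS[if (is.na(i)) 6L else i] / 100  # "other" gets carbon mass
  c(el, deg, chg, hyb, as.numeric(aromatic), hs, mass)
}

#' Featurize one bond
#'
#' @param bondType one of "single", "double", "triple", "aromatic"; anything
#'   else maps to "single" (every bond gets a bucket).
#' @param conjugated logical conjugation flag.
#' @param inRing logical ring-membership flag.
#' @return numeric vector of length \code{bondFeatureLength()} with exactly
#'   one bond-type bit set.
#' @examples
#' featurizeBond("aromatic", TRUE, TRUE)
#' @export
featurizeBond <- function(bondType, conjugated, inRing) {
  bt <- as.numeric(.BOND_TYPES == bondType)
  if (!any(bt > 0)) bt[1L] <- 1
  c(bt, as.numeric(conjugated), as.numeric(inRing))
}

.obConvert <- function(from, to, text) {
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, text))
  out
}

#' Canonicalize a SMILES string
#'
#' Validates and canonicalizes through the chemistry toolkit. Unparseable or
#' empty input raises an error naming the offending string.
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES.
#' @examples
#' canonicalSmiles("c1ccccc1C")  # "Cc1ccccc1"
#' @export
canonicalSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    stop("cannot parse SMILES: empty input")
  s <- trimws(smiles)
  # Open Babel silently drops unmatched parentheses/brackets; reject up front
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")") ||
      sum(chars == "[") != sum(chars == "]"))
    stop("cannot parse SMILES '", smiles, "': unbalanced brackets")
  out <- .obConvert("SMI", "CAN", paste0(s, "\n"))
  can <- sub("[\t\n].*$", "", out)
  if (!nzchar(can)) stop("cannot parse SMILES '", smiles, "'")
  can
}

# Tokenize the atoms of a (canonical) SMILES string, in order of appearance.
# Returns a data.frame with the element symbol and the aromatic flag taken
# from the lower-case convention. Bond/ring/branch symbols are skipped.
.smilesAtomTokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elements <- character(0)
  aromatic <- logical(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- sub("^[0-9]*", "", body)           # isotope
      m <- regmatches(body, regexpr("^[A-Za-z][a-z]?", body))[1]
      # two-letter symbols are Capital+lower; a lone lower-case letter or a
      # lower-case pair like "nH" means an aromatic one-letter element
      first <- substr(m, 1L, 1L)
      if (first %in% letters) {
        elements <- c(elements, toupper(first))
        aromatic <- c(aromatic, TRUE)
      } else if (nchar(m) == 2L &&
                 paste0(first, substr(m, 2L, 2L)) %in% .ELEMENTS &&
                 !(substr(m, 2L, 2L) == "H" && !paste0(first, "H") %in% .ELEMENTS)) {
        elements <- c(elements, m)
        aromatic <- c(aromatic, FALSE)
      } else {
        elements <- c(elements, first)
        aromatic <- c(aromatic, FALSE)
      }
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      elements <- c(elements, paste0(ch, chars[i + 1L]))
      aromatic <- c(aromatic, FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      elements <- c(elements, ch)
      aromatic <- c(aromatic, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      elements <- c(elements, toupper(ch))
      aromatic <- c(aromatic, TRUE)
      i <- i + 1L
    } else {
      i <- i + 1L   # ring digits, bonds, branches, dots, % closures
    }
  }
  data.frame(element = elements, aromatic = aromatic,
             stringsAsFactors = FALSE)
}

# Read the first V2000 molblock of an SDF string: elements, bonds
# (from/to/order) and formal charges (M CHG lines).
.readMolblock <- function(sdftext) {
  lines <- strsplit(sdftext, "\n", fixed = TRUE)[[1]]
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na)) stop("malformed molblock")
  atomLines <- lines[seq_len(na) + 4L]
  elements <- trimws(substr(atomLines, 32L, 34L))
  bonds <- matrix(integer(0), 0L, 3L)
  if (nb > 0L) {
    bondLines <- lines[seq_len(nb) + 4L + na]
    bonds <- cbind(as.integer(substr(bondLines, 1L, 3L)),
                   as.integer(substr(bondLines, 4L, 6L)),
                   as.integer(substr(bondLines, 7L, 9L)))
  }
  charges <- integer(na)
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
    k <- fields[1L]
    for (p in seq_len(k))
      charges[fields[2L * p]] <- fields[2L * p + 1L]
  }
  list(elements = elements, bonds = bonds, charges = charges)
}

# implicit hydrogen count under a simplified valence model
.implicitH <- function(element, charge, bondOrderSum) {
  val <- .VALENCE[element]
  if (is.na(val)) return(0L)
  val <- switch(element,
    C = val - abs(charge),
    B = val - charge,
    val + charge)  # N, P, O, S, halogens: protonation adds a slot
  max(0L, as.integer(round(val - bondOrderSum)))
}

#' Parse a SMILES string into a directed molecular graph
#'
#' The molecule is canonicalized first, so atom order follows the toolkit's
#' canonical atom order and two spellings of the same molecule give identical
#' graphs. Every chemical bond yields two directed edges carrying identical
#' bond features. Hydrogens stay implicit.
#'
#' @param smiles a single SMILES string.
#' @return a [MolecularGraph-class] object.
#' @examples
#' g <- smilesToGraph("c1ccccc1")
#' numAtoms(g)            # 6
#' nrow(edgeList(g))      # 12 directed edges
#' @export
smilesToGraph <- function(smiles) {
  can <- canonicalSmiles(smiles)
  sdftext <- .obConvert("SMI", "SDF", paste0(can, "\n"))
  mb <- .readMolblock(sdftext)
  m <- length(mb$elements)
  tok <- .smilesAtomTokens(can)
  if (nrow(tok) != m)
    stop("internal parse mismatch for '", can, "': ", nrow(tok),
         " SMILES atoms vs ", m, " molblock atoms")
  if (any(tok$element != mb$elements))
    stop("internal parse mismatch for '", can, "': element order differs")
  aromaticAtom <- tok$aromatic

  nb <- nrow(mb$bonds)
  ringBondU <- logical(nb)
  if (nb > 0L) {
    ig <- igraph::graph_from_edgelist(mb$bonds[, 1:2, drop = FALSE],
                                      directed = FALSE)
    if (igraph::vcount(ig) < m)
      ig <- igraph::add_vertices(ig, m - igraph::vcount(ig))
    ringBondU[] <- TRUE
    ringBondU[igraph::bridges(ig)] <- FALSE
  }
  aromaticBondU <- ringBondU & aromaticAtom[mb$bonds[, 1L]] &
    aromaticAtom[mb$bonds[, 2L]]

  orderSum <- numeric(m)
  degree <- integer(m)
  if (nb > 0L) {
    for (b in seq_len(nb)) {
      u <- mb$bonds[b, 1L]; v <- mb$bonds[b, 2L]; o <- mb$bonds[b, 3L]
      orderSum[u] <- orderSum[u] + o
      orderSum[v] <- orderSum[v] + o
      degree[u] <- degree[u] + 1L
      degree[v] <- degree[v] + 1L
    }
  }
  nDouble <- integer(m); nTriple <- integer(m)
  if (nb > 0L) {
    for (b in seq_len(nb)) {
      if (mb$bonds[b, 3L] == 2L) {
        nDouble[mb$bonds[b, 1L]] <- nDouble[mb$bonds[b, 1L]] + 1L
        nDouble[mb$bonds[b, 2L]] <- nDouble[mb$bonds[b, 2L]] + 1L
      } else if (mb$bonds[b, 3L] == 3L) {
        nTriple[mb$bonds[b, 1L]] <- nTriple[mb$bonds[b, 1L]] + 1L
        nTriple[mb$bonds[b, 2L]] <- nTriple[mb$bonds[b, 2L]] + 1L
      }
    }
  }
  hyb <- ifelse(nTriple > 0L | nDouble >= 2L, "sp",
         ifelse(aromaticAtom | nDouble == 1L, "sp2", "sp3"))
  mainGroup <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
                 "Si", "Se", "As")
  hyb[!(mb$elements %in% mainGroup)] <- "other"

  numH <- integer(m)
  for (a in seq_len(m))
    numH[a] <- .implicitH(mb$elements[a], mb$charges[a], orderSum[a])

  af <- matrix(0, m, atomFeatureLength())
  for (a in seq_len(m))
    af[a, ] <- featurizeAtom(mb$elements[a], degree[a], mb$charges[a],
                             hyb[a], aromaticAtom[a], numH[a])

  # conjugation: both bond atoms carry unsaturation beyond this bond
  unsatCount <- nDouble + nTriple + vapply(seq_len(m), function(a) {
    if (nb == 0L) return(0L)
    sum(aromaticBondU[mb$bonds[, 1L] == a | mb$bonds[, 2L] == a])
  }, integer(1))
  conjU <- logical(nb)
  if (nb > 0L) {
    for (b in seq_len(nb)) {
      if (aromaticBondU[b]) { conjU[b] <- TRUE; next }
      o <- mb$bonds[b, 3L]
      self <- if (o >= 2L) 1L else 0L
      u <- mb$bonds[b, 1L]; v <- mb$bonds[b, 2L]
      conjU[b] <- (unsatCount[u] - self) > 0L && (unsatCount[v] - self) > 0L
    }
  }

  edges <- matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("src", "dst")))
  bf <- matrix(numeric(0), 0L, bondFeatureLength())
  reverseIndex <- integer(0)
  bondOrder <- numeric(0); aromaticBond <- logical(0); ringBond <- logical(0)
  if (nb > 0L) {
    edges <- matrix(0L, 2L * nb, 2L, dimnames = list(NULL, c("src", "dst")))
    bf <- matrix(0, 2L * nb, bondFeatureLength())
    reverseIndex <- integer(2L * nb)
    bondOrder <- numeric(2L * nb)
    aromaticBond <- logical(2L * nb)
    ringBond <- logical(2L * nb)
    for (b in seq_len(nb)) {
      u <- mb$bonds[b, 1L]; v <- mb$bonds[b, 2L]; o <- mb$bonds[b, 3L]
      bt <- if (aromaticBondU[b]) "aromatic"
            else .BOND_TYPES[min(o, 3L)]
      feat <- featurizeBond(bt, conjU[b], ringBondU[b])
      i1 <- 2L * b - 1L; i2 <- 2L * b
      edges[i1, ] <- c(u, v); edges[i2, ] <- c(v, u)
      bf[i1, ] <- feat; bf[i2, ] <- feat
      reverseIndex[i1] <- i2; reverseIndex[i2] <- i1
      bondOrder[c(i1, i2)] <- o
      aromaticBond[c(i1, i2)] <- aromaticBondU[b]
      ringBond[c(i1, i2)] <- ringBondU[b]
    }
  }

  new("MolecularGraph",
      smiles = can, atomFeatures = af, bondFeatures = bf, edges = edges,
      reverseIndex = reverseIndex, elements = mb$elements,
      aromaticAtom = aromaticAtom, formalCharge = as.integer(mb$charges),
      numH = numH, bondOrder = bondOrder, aromaticBond = aromaticBond,
      ringBond = ringBond)
}
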