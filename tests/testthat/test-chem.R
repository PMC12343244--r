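# SMILES parsing into directed molecular graphs and featurization.

test_that("parsing produces the expected directed graph shapes", {
  g <- smilesToGraph("C")
  expect_equal(numAtoms(g), 1L)
  expect_equal(nrow(edgeList(g)), 0L)

  g <- smilesToGraph("CC")
  expect_equal(numAtoms(g), 2L)
  expect_equal(nrow(edgeList(g)), 2L)
  expect_equal(g@reverseIndex, c(2L, 1L))
  expect_equal(edgeList(g)[1L, ], c(src = 1L, dst = 2L))
  expect_equal(edgeList(g)[2L, ], c(src = 2L, dst = 1L))
})

test_that("aromatic perception matches benzene chemistry", {
  g <- smilesToGraph("c1ccccc1")
  expect_equal(numAtoms(g), 6L)
  expect_equal(nrow(edgeList(g)), 12L)
  expect_true(all(g@aromaticAtom))
  aromaticBit <- bondFeatures(g)[, 4L]  # bond-type one-hot: aromatic slot
  expect_true(all(aromaticBit == 1))
  # aromaticity flag sits after element, degree, charge and hybrid blocks
  flagCol <- 101L + 6L + 6L + 4L + 1L
  expect_true(all(atomFeatures(g)[, flagCol] == 1))
})

test_that("malformed and empty SMILES raise parse errors naming the input", {
  expect_error(smilesToGraph("C("), "C\\(")
  expect_error(smilesToGraph(""), "empty")
  expect_error(smilesToGraph("xyz123"), "cannot parse")
  expect_error(canonicalSmiles("C1CC"), "cannot parse")
})

test_that("atom featurization is deterministic with the documented layout", {
  v <- featurizeAtom("C", 4L, 0L, "sp3", FALSE, 0L)
  expect_length(v, atomFeatureLength())
  expect_equal(v[6L], 1)                      # carbon is element 6
  expect_equal(sum(v[1:101]), 1)              # one element bit
  expect_equal(v[length(v)], 12.011 / 100)    # scaled mass
  expect_identical(v, featurizeAtom("C", 4L, 0L, "sp3", FALSE, 0L))

  # unknown element falls into the "other" bucket, never an error
  vu <- featurizeAtom("Xx", 1L, 0L, "other", FALSE, 0L)
  expect_equal(vu[101L], 1)

  # every one-hot block has at most one nonzero entry; all entries bounded
  blocks <- list(1:101, 102:107, 108:113, 114:117, 119:123)
  for (b in blocks) expect_lte(sum(v[b] != 0), 1L)
  expect_true(all(v >= 0 & v <= 3))
})

test_that("aromatic ring nitrogen carries the aromaticity flag", {
  g <- smilesToGraph("c1ccncc1")
  flagCol <- 101L + 6L + 6L + 4L + 1L
  nIdx <- which(g@elements == "N")
  expect_equal(atomFeatures(g)[nIdx, flagCol], 1)
})

test_that("bond featurization encodes type, conjugation and ring state", {
  expect_equal(featurizeBond("single", FALSE, FALSE), c(1, 0, 0, 0, 0, 0))
  expect_equal(featurizeBond("aromatic", TRUE, TRUE), c(0, 0, 0, 1, 1, 1))
  g <- smilesToGraph("C=C")
  expect_equal(bondFeatures(g)[1L, ], c(0, 1, 0, 0, 0, 0))
  # all bond types map to a bucket: exactly one type bit everywhere
  for (smi in c("CCO", "C#N", "c1ccccc1", "CC=CC"))
    expect_true(all(rowSums(
      bondFeatures(smilesToGraph(smi))[, 1:4, drop = FALSE]) == 1))
})

test_that("reverse edges form a fixed-point-free involution with shared features", {
  for (smi in c("CCO", "c1ccccc1", "CC(=O)Nc1ccccc1", "C1CCC2CCCCC2C1")) {
    g <- smilesToGraph(smi)
    rev <- g@reverseIndex
    expect_identical(rev[rev], seq_along(rev))
    expect_false(any(rev == seq_along(rev)))
    expect_equal(bondFeatures(g), bondFeatures(g)[rev, , drop = FALSE])
    expect_equal(edgeList(g)[rev, 1L], unname(edgeList(g)[, 2L]))
  }
})

test_that("two spellings of one molecule give identical graphs", {
  pairs <- list(c("Cc1ccccc1", "c1ccccc1C"),
                c("OCC", "CCO"),
                c("N(c1ccccc1)C(C)=O", "CC(=O)Nc1ccccc1"))
  for (p in pairs) {
    g1 <- smilesToGraph(p[1L])
    g2 <- smilesToGraph(p[2L])
    expect_identical(g1@smiles, g2@smiles)
    expect_equal(atomFeatures(g1), atomFeatures(g2))
    expect_equal(bondFeatures(g1), bondFeatures(g2))
    expect_equal(edgeList(g1), edgeList(g2))
  }
})

test_that("feature widths are constant across a molecule set", {
  smi <- generateMolecules(25, seed = 7)
  widths <- vapply(smi, function(s) ncol(atomFeatures(smilesToGraph(s))),
                   integer(1))
  expect_true(all(widths == atomFeatureLength()))
  bwidths <- vapply(smi, function(s) ncol(bondFeatures(smilesToGraph(s))),
                    integer(1))
  expect_true(all(bwidths == bondFeatureLength()))
})

test_that("implicit hydrogen counts follow the valence model", {
  g <- smilesToGraph("CCO")
  expect_equal(g@numH, c(3L, 2L, 1L))
  expect_equal(smilesToGraph("C")@numH, 4L)
  expect_equal(smilesToGraph("[NH4+]")@numH, 4L)
  nIdx <- which(smilesToGraph("c1ccncc1")@elements == "N")
  expect_equal(smilesToGraph("c1ccncc1")@numH[nIdx], 0L)
})
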