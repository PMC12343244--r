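# Communicative message passing: aggregation semantics, edge updates,
# oracle equivalence, padding, and locality.

test_that("incoming aggregation is sum times elementwise max", {
  e <- rbind(c(1, 0), c(0, 1))
  # two incoming edges: SUM = [1,1], elementwise MAX = [1,1]
  expect_equal(aggregateIncoming(e, list(1:2))[1L, ], c(1, 1))
  # a single incoming edge gives h * h
  expect_equal(aggregateIncoming(rbind(c(2, -3)), list(1L))[1L, ], c(4, 9))
  # no incoming edges: zero vector
  expect_equal(aggregateIncoming(e, list(integer(0)))[1L, ], c(0, 0))
})

test_that("node update is additive", {
  h <- rbind(c(1, 2))
  expect_equal(updateNode(h, h * 0), h)
  expect_equal(updateNode(h, rbind(c(3, -1))), rbind(c(4, 1)))
  expect_equal(updateNode(updateNode(h, h), h), 3 * h)  # linearity
  expect_error(updateNode(h, matrix(0, 2L, 2L)), "shape")
})

test_that("edge update subtracts the reverse edge and rectifies", {
  e0 <- rbind(c(0.5, 0.5))
  # source equals reverse: difference vanishes, ReLU(e0) remains
  expect_equal(updateEdge(rbind(c(1, 1)), rbind(c(1, 1)), e0, diag(2)), e0)
  # identity weights, zero initial state: plain ReLU of the difference
  expect_equal(
    updateEdge(rbind(c(1, -2)), rbind(c(0, 0)), rbind(c(0, 0)), diag(2)),
    rbind(c(1, 0)))
  expect_error(updateEdge(rbind(c(1, 1)), rbind(c(1, 1)), e0, diag(3)),
               "width")
})

test_that("the vectorized encoder matches the per-node/per-edge loop oracle", {
  set.seed(21)
  smallMols <- c("C", "CC", "CCO", "CCC", "C=C", "CC#N", "CC(C)C",
                 "OCC", "CNC", "CCCC", "C=O", "NCC")
  for (trial in 1:12) {
    smi <- sample(smallMols, 1L)
    model <- tinyModel(depth = sample(0:3, 1L), seed = trial)
    g <- smilesToGraph(smi)
    enc <- encodeMolecule(model, g)
    ref <- oracleEncoder(model@params, g, model@config$depth)
    expect_equal(enc$atomEmbeddings, ref, tolerance = 1e-6,
                 label = paste("encoder vs oracle on", smi))
  }
})

test_that("encoding respects the degenerate and deterministic contracts", {
  model <- tinyModel()
  enc <- encodeMolecule(model, smilesToGraph("C"))
  expect_equal(dim(enc$atomEmbeddings), c(1L, 8L))
  expect_true(all(is.finite(enc$moleculeEmbedding)))

  # same molecule, two spellings: identical embedding via canonical order
  e1 <- encodeMolecule(model, smilesToGraph("Cc1ccccc1"))
  e2 <- encodeMolecule(model, smilesToGraph("c1ccccc1C"))
  expect_equal(e1$moleculeEmbedding, e2$moleculeEmbedding)

  expect_error(encodeMolecule(model,
    new("MolecularGraph", smiles = "", elements = character(0),
        atomFeatures = matrix(0, 0L, atomFeatureLength()),
        bondFeatures = matrix(0, 0L, bondFeatureLength()),
        edges = matrix(0L, 0L, 2L), reverseIndex = integer(0),
        aromaticAtom = logical(0), formalCharge = integer(0),
        numH = integer(0), bondOrder = numeric(0),
        aromaticBond = logical(0), ringBond = logical(0))), "empty")
})

test_that("outputs stay finite across random molecules and seeds", {
  smi <- generateMolecules(12, seed = 9)
  for (s in seq_len(3L)) {
    model <- tinyModel(seed = s)
    for (m in smi) {
      enc <- encodeMolecule(model, smilesToGraph(m))
      expect_true(all(is.finite(enc$atomEmbeddings)))
      expect_true(all(is.finite(enc$moleculeEmbedding)))
    }
  }
})

test_that("K message-passing rounds only see the K-hop neighborhood", {
  model <- tinyModel(depth = 2L)
  g <- smilesToGraph("CCCCCC")   # path of six carbons
  base <- encodeMolecule(model, g)$atomEmbeddings
  # perturb the far end of the chain (> K bonds from atom 1)
  g2 <- g
  g2@atomFeatures[6L, ] <- g2@atomFeatures[6L, ] + 0.5
  pert <- encodeMolecule(model, g2)$atomEmbeddings
  expect_equal(pert[1L, ], base[1L, ])      # unchanged within 2 hops
  expect_false(isTRUE(all.equal(pert[5L, ], base[5L, ])))  # neighbor moved
})

test_that("padding appends exact zero rows up to the batch maximum", {
  xs <- list(matrix(1, 3L, 2L), matrix(2, 5L, 2L))
  pb <- padBatch(xs)
  expect_equal(dim(pb$features), c(2L, 5L, 2L))
  expect_equal(pb$atomCounts, c(3L, 5L))
  expect_true(all(pb$features[1L, 4:5, ] == 0))
  expect_equal(pb$features[2L, , ], xs[[2L]], ignore_attr = TRUE)

  single <- padBatch(list(matrix(3, 4L, 2L)))
  expect_equal(single$features[1L, , ], matrix(3, 4L, 2L),
               ignore_attr = TRUE)
  expect_error(padBatch(list(matrix(1, 2L, 2L), matrix(1, 2L, 3L))),
               "width")
})
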