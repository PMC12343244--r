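# Chemistry-rule decomposition, vocabulary, and the motif graph matrices.

fragSizes <- function(frags)
  sort(vapply(frags, function(f) length(f$atomIndices), integer(1)))

fragKeys <- function(frags)
  sort(vapply(frags, `[[`, character(1), "motifKey"))

test_that("decomposition handles the canonical rule cases", {
  # no ring-substituent bond, no branching acyclic atom: one fragment
  frags <- decomposeMotifs(smilesToGraph("C1CC1"))
  expect_length(frags, 1L)
  expect_equal(frags[[1L]]$atomIndices, 1:3)

  # toluene: ring system separates from its methyl substituent
  frags <- decomposeMotifs(smilesToGraph("Cc1ccccc1"))
  expect_equal(fragSizes(frags), c(1L, 6L))
  expect_equal(fragKeys(frags), c("C", "c1ccccc1"))

  # neopentane: central carbon has four heavy neighbors -> five singletons
  frags <- decomposeMotifs(smilesToGraph("CC(C)(C)C"))
  expect_length(frags, 5L)
  expect_equal(fragSizes(frags), rep(1L, 5L))

  # single atom: one singleton fragment
  expect_length(decomposeMotifs(smilesToGraph("C")), 1L)

  # fused bicyclic stays one intact fragment
  expect_length(decomposeMotifs(smilesToGraph("c1ccc2ccccc2c1")), 1L)
})

test_that("the biaryl amide case study keeps its ring systems intact", {
  frags <- decomposeMotifs(smilesToGraph(
    "O=C(NCc1cccnc1)C(Cc1cc2cc(ccc2nc1N)-c1ccccc1C)C"))
  keys <- vapply(frags, `[[`, character(1), "motifKey")
  expect_true("c1cccnc1" %in% keys)          # pyridine ring intact
  expect_true("c1ccccc1" %in% keys)          # pendant phenyl intact
  expect_true(any(vapply(frags, function(f)
    length(f$atomIndices) == 10L, logical(1))))  # fused bicyclic intact
  # fragments partition the atoms
  expect_setequal(unlist(lapply(frags, `[[`, "atomIndices")),
                  seq_len(numAtoms(smilesToGraph(
                    "O=C(NCc1cccnc1)C(Cc1cc2cc(ccc2nc1N)-c1ccccc1C)C"))))
})

test_that("decomposition matches the broken-bond reference on the curated suite", {
  for (smi in curatedSuite()) {
    g <- smilesToGraph(smi)
    got <- lapply(decomposeMotifs(g), `[[`, "atomIndices")
    expect_identical(partitionKey(got), partitionKey(oracleDecompose(g)),
                     label = paste("partition of", smi))
  }
})

test_that("decomposition is invariant to the SMILES spelling", {
  spellings <- list(
    c("Cc1ccccc1", "c1ccccc1C", "c1cc(C)ccc1"),
    c("CC(C)(C)c1ccccc1", "c1ccccc1C(C)(C)C"),
    c("OC(=O)c1ccc(N)cc1", "Nc1ccc(C(O)=O)cc1"))
  for (sp in spellings) {
    keys <- lapply(sp, function(s)
      fragKeys(decomposeMotifs(smilesToGraph(s))))
    for (k in keys[-1L]) expect_identical(k, keys[[1L]])
  }
})

test_that("vocabulary construction is deduplicated, sorted and reloadable", {
  v <- buildMotifVocabulary("Cc1ccccc1")
  expect_equal(vocabSize(v), 3L)            # ring + methyl + [UNK]
  expect_equal(unkIndex(v), 3L)

  vdup <- buildMotifVocabulary(c("Cc1ccccc1", "Cc1ccccc1", "c1ccccc1C"))
  expect_identical(vdup@keys, v@keys)

  expect_error(buildMotifVocabulary(character(0)), "empty")
  expect_warning(v2 <- buildMotifVocabulary(c("Cc1ccccc1", "notasmiles")),
                 "unparseable")
  expect_identical(v2@keys, v@keys)

  tf <- withr::local_tempfile(fileext = ".tsv")
  writeMotifVocabulary(v, tf)
  expect_identical(readMotifVocabulary(tf)@keys, v@keys)

  # unknown motifs map to the reserved index
  expect_equal(motifIndex(v, c("C", "never-seen")), c(1L, unkIndex(v)))
})

test_that("the motif graph of toluene has the documented structure", {
  g <- smilesToGraph("Cc1ccccc1")
  v <- buildMotifVocabulary("Cc1ccccc1")
  mg <- buildMotifGraph(g, vocab = v)
  expect_equal(mg@n, 2L)
  expect_equal(dim(adjacencyMatrix(mg)), c(3L, 3L))
  A <- adjacencyMatrix(mg)
  expect_equal(A[1L, 2L], 1L)               # the two motifs are adjacent
  expect_true(all(A[3L, 1:2] == 1L))        # global adjacent to every motif
  F <- associationMatrix(mg)
  expect_equal(dim(F), c(2L, 7L))
  expect_setequal(rowSums(F), c(1, 6))
  expect_true(all(colSums(F) == 1))
  expect_true(all(rowSums(mg@onehots) == 1))
})

test_that("motifs unseen by the vocabulary get the [UNK] bit", {
  v <- buildMotifVocabulary("CCO")          # no aromatic motifs
  mg <- buildMotifGraph(smilesToGraph("Cc1ccccc1"), vocab = v)
  unkRows <- which(mg@motifKeys == "c1ccccc1")
  expect_equal(mg@motifIndices[unkRows], unkIndex(v))
  expect_equal(mg@onehots[unkRows, unkIndex(v)], 1)
})

test_that("a single-fragment molecule yields the degenerate motif graph", {
  v <- tinyVocab()
  mg <- buildMotifGraph(smilesToGraph("C1CC1"), vocab = v)
  expect_equal(dim(adjacencyMatrix(mg)), c(2L, 2L))
  D <- distanceMatrix(mg)
  expect_true(all(D[row(D) != col(D)] == 1))
})

test_that("fragments that do not partition the molecule are rejected", {
  g <- smilesToGraph("CCO")
  bad <- list(list(atomIndices = 1:2, motifKey = "CC"))
  expect_error(buildMotifGraph(g, bad, tinyVocab()), "partition")
  outside <- list(list(atomIndices = c(1L, 9L), motifKey = "CC"))
  expect_error(buildMotifGraph(g, outside, tinyVocab()), "outside")
})

test_that("shortest-path distances match Floyd-Warshall on random graphs", {
  set.seed(11)
  for (trial in 1:25) {
    n <- sample(2:12, 1L)
    A <- matrix(0L, n, n)
    edges <- which(upper.tri(A), arr.ind = TRUE)
    pick <- edges[stats::runif(nrow(edges)) < 0.35, , drop = FALSE]
    A[pick] <- 1L
    A <- A + t(A)
    expect_equal(shortestPathMatrix(A), oracleFloydWarshall(A),
                 ignore_attr = TRUE)
  }
})

test_that("shortest-path conventions: hops, sentinel, global distance", {
  # path graph on 3 motifs: two hops end to end
  A <- matrix(0L, 3L, 3L); A[1L, 2L] <- A[2L, 1L] <- A[2L, 3L] <- A[3L, 2L] <- 1L
  expect_equal(shortestPathMatrix(A)[1L, 3L], 2L)
  # disconnected pair gets the sentinel n + 1
  A2 <- matrix(0L, 2L, 2L)
  expect_equal(shortestPathMatrix(A2)[1L, 2L], 3L)
})

test_that("motif matrices satisfy their contracts on generated molecules", {
  smi <- generateMolecules(30, seed = 3)
  v <- buildMotifVocabulary(smi)
  for (s in smi) {
    g <- smilesToGraph(s)
    mg <- buildMotifGraph(g, vocab = v)
    A <- adjacencyMatrix(mg); D <- distanceMatrix(mg)
    n <- mg@n
    expect_equal(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_equal(D, t(D))
    expect_true(all(D[mg@globalIndex, -mg@globalIndex] == 1))
    expect_true(all(colSums(associationMatrix(mg)) == 1))
    expect_equal(sum(associationMatrix(mg)), numAtoms(g))
    # A => D consistency off the global row
    core <- seq_len(n)
    expect_true(all((A[core, core] == 1) == (D[core, core] == 1)))
    # D equals the Floyd-Warshall oracle with the global node appended
    Dref <- oracleFloydWarshall(A[core, core, drop = FALSE])
    expect_equal(D[core, core], Dref, ignore_attr = TRUE)
  }
})

test_that("motif graphs export as JSON", {
  mg <- buildMotifGraph(smilesToGraph("Cc1ccccc1"), vocab = tinyVocab())
  txt <- exportMotifGraph(mg)
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_equal(parsed$n, 2L)
  expect_length(parsed$A, 3L)
  expect_length(parsed$A[[1L]], 3L)
  expect_equal(parsed$global_index, 3L)
})
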