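# Model construction and the full (inference) forward pass. Training runs
# an equivalent pass on the autodiff tape (train.R); the two are checked
# against each other in the test suite.

#' Model configuration
#'
#' Assembles and validates the configuration of a dual-granularity model.
#' Defaults: hidden size 256 shared by the encoder and the attention stack,
#' 3 message-passing rounds, a 2-layer attention stack with 4 heads per
#' channel, the recurrent readout, multiplicative masks as printed in the
#' model equations, and an initial residual scale of 0.1.
#'
#' @param hiddenSize shared embedding width d (even; d/2 divisible by
#'   \code{headsPerChannel}).
#' @param depth message-passing rounds K.
#' @param readout "gru_mean" (bidirectional recurrent pass then mean) or
#'   "mean".
#' @param attnLayers stacked global-local attention layers.
#' @param headsPerChannel attention heads in each channel.
#' @param alphaInit initial value of the learnable residual scale.
#' @param maskMode "multiplicative", "additive_neg_inf" or "none".
#' @param distanceTransform "identity" (raw hop counts) or "reciprocal".
#' @param perMotifNorm normalize the atomic projection by per-motif atom
#'   counts instead of the molecule total.
#' @param selfLoops add the identity to the adjacency mask so motifs can
#'   attend to themselves in the local channel.
#' @param useDistance,useAdjacency,useGlTransformer ablation switches: an
#'   all-ones distance mask, an all-ones adjacency mask, or bypassing the
#'   attention stack entirely (the molecule embedding passes through).
#' @param pooling how the refined motif matrix collapses to a vector:
#'   "global" row or "mean".
#' @param nTargets number of prediction targets.
#' @param taskType "regression" or "classification".
#' @return named list of validated configuration values.
#' @export
motifFuseConfig <- function(hiddenSize = 256L, depth = 3L,
                            readout = c("gru_mean", "mean"),
                            attnLayers = 2L, headsPerChannel = 4L,
                            alphaInit = 0.1,
                            maskMode = c("multiplicative",
                                         "additive_neg_inf", "none"),
                            distanceTransform = c("identity", "reciprocal"),
                            perMotifNorm = FALSE, selfLoops = FALSE,
                            useDistance = TRUE, useAdjacency = TRUE,
                            useGlTransformer = TRUE,
                            pooling = c("global", "mean"),
                            nTargets = 1L,
                            taskType = c("regression", "classification")) {
  hiddenSize <- as.integer(hiddenSize)
  if (hiddenSize %% 2L != 0L)
    stop("hiddenSize must be even (the attention stack splits it in two)")
  headsPerChannel <- as.integer(headsPerChannel)
  if ((hiddenSize %/% 2L) %% headsPerChannel != 0L)
    stop("hiddenSize/2 must be divisible by headsPerChannel")
  if (depth < 0L) stop("depth must be nonnegative")
  list(hiddenSize = hiddenSize, depth = as.integer(depth),
       readout = match.arg(readout), attnLayers = as.integer(attnLayers),
       headsPerChannel = headsPerChannel, alphaInit = alphaInit,
       maskMode = match.arg(maskMode),
       distanceTransform = match.arg(distanceTransform),
       perMotifNorm = isTRUE(perMotifNorm), selfLoops = isTRUE(selfLoops),
       useDistance = isTRUE(useDistance),
       useAdjacency = isTRUE(useAdjacency),
       useGlTransformer = isTRUE(useGlTransformer),
       pooling = match.arg(pooling),
       nTargets = as.integer(nTargets), taskType = match.arg(taskType))
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Construct a dual-granularity model with freshly initialized weights
#'
#' Builds all learnable parameters (uniform Glorot initialization, biases at
#' zero, layer-norm affine at identity, alpha at its configured start) for
#' the encoder, the motif fusion, the attention stack and the linear
#' prediction head.
#'
#' @param vocab a [MotifVocabulary-class]; its size fixes the identity
#'   embedding table ([UNK] and [GLOBAL] own one row each).
#' @param config a list from [motifFuseConfig()].
#' @param seed integer seed for reproducible initialization.
#' @return a [MotifFuseModel-class].
#' @export
motifFuseModel <- function(vocab, config = motifFuseConfig(), seed = 0L) {
  d <- config$hiddenSize
  dh2 <- d %/% 2L
  L <- vocabSize(vocab)
  p <- list()
  withRNG(seed, {
    p$Watom <- .glorot(atomFeatureLength(), d)
    p$batom <- matrix(0, 1L, d)
    p$Wbond <- .glorot(atomFeatureLength() + bondFeatureLength(), d)
    p$bbond <- matrix(0, 1L, d)
    for (k in seq_len(config$depth))
      p[[paste0("Wk_", k)]] <- .glorot(d, d)
    p$Wcomm <- .glorot(d, d)
    p$bcomm <- matrix(0, 1L, d)
    if (identical(config$readout, "gru_mean")) {
      for (dir in c("f", "b")) {
        for (gate in c("z", "r", "h")) {
          p[[paste0("gru_", dir, "_W", gate)]] <- .glorot(d, dh2)
          p[[paste0("gru_", dir, "_U", gate)]] <- .glorot(dh2, dh2)
          p[[paste0("gru_", dir, "_b", gate)]] <- matrix(0, 1L, dh2)
        }
      }
    }
    p$WG <- .glorot(d, d)
    p$bG <- matrix(0, 1L, d)
    p$emb <- .glorot(L + 1L, d)      # motif identities + [GLOBAL] (last row)
    for (l in seq_len(config$attnLayers)) {
      for (ch in c("g", "l")) {
        p[[paste0("attn", l, "_", ch, "_Wq")]] <- .glorot(dh2, dh2)
        p[[paste0("attn", l, "_", ch, "_Wk")]] <- .glorot(dh2, dh2)
        p[[paste0("attn", l, "_", ch, "_Wv")]] <- .glorot(dh2, dh2)
      }
      p[[paste0("ln", l, "_gamma")]] <- matrix(1, 1L, d)
      p[[paste0("ln", l, "_beta")]] <- matrix(0, 1L, d)
    }
    p$alpha <- matrix(config$alphaInit, 1L, 1L)
    p$Whead <- .glorot(d, config$nTargets)
    p$bhead <- matrix(0, 1L, config$nTargets)
  })
  new("MotifFuseModel", params = p, config = config, vocab = vocab)
}

# full forward pass for one prepared molecule (inference path).
# entry: list(graph, mg) as produced by prepareDataset().
.forwardOne <- function(model, entry, withAttention = FALSE) {
  cfg <- model@config
  p <- model@params
  enc <- encodeMolecule(model, entry$graph)
  M <- enc$moleculeEmbedding
  attention <- NULL
  if (cfg$useGlTransformer) {
    mg <- entry$mg
    proj <- projectAtomsToMotifs(mg@F, enc$atomEmbeddings, p$WG, p$bG[1L, ],
                                 m = numAtoms(entry$graph),
                                 perMotif = cfg$perMotifNorm)
    ident <- p$emb[mg@motifIndices, , drop = FALSE]
    H <- fuseMotifFeatures(proj, ident, p$emb[nrow(p$emb), ])
    masks <- .attentionMasks(mg@A, mg@D, cfg)
    attention <- vector("list", cfg$attnLayers)
    for (l in seq_len(cfg$attnLayers)) {
      res <- glLayer(H, masks$local, masks$global, .glLayerWeights(p, l),
                     heads = cfg$headsPerChannel, maskMode = cfg$maskMode)
      H <- res$output
      if (withAttention)
        attention[[l]] <- list(global = res$globalAttention,
                               local = res$localAttention)
    }
    Mfinal <- finalizeRepresentation(M, H, p$alpha[1L, 1L],
                                     globalIndex = mg@globalIndex,
                                     pooling = cfg$pooling)
  } else {
    Mfinal <- M
  }
  logits <- as.numeric(Mfinal %*% p$Whead + p$bhead[1L, ])
  list(representation = Mfinal, logits = logits, attention = attention,
       encoder = enc)
}

#' Predict properties for a list of SMILES
#'
#' Parses, decomposes and encodes each molecule with the trained model.
#' Unparseable SMILES are reported in the \code{error} column rather than
#' silently dropped.
#'
#' @param model a trained [MotifFuseModel-class].
#' @param smiles character vector of SMILES.
#' @return data.frame with one row per input: the canonical SMILES, raw
#'   outputs (\code{logit_*}; sigmoid probabilities \code{prob_*} are added
#'   for classification) and an \code{error} column (NA when prediction
#'   succeeded).
#' @export
predictMolecules <- function(model, smiles) {
  cfg <- model@config
  nt <- cfg$nTargets
  out <- data.frame(smiles = smiles, canonical = NA_character_,
                    stringsAsFactors = FALSE)
  logitCols <- matrix(NA_real_, length(smiles), nt)
  errs <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    res <- tryCatch({
      entry <- .prepareEntry(smiles[i], model@vocab)
      fw <- .forwardOne(model, entry)
      list(can = entry$graph@smiles, logits = fw$logits)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[i] <- conditionMessage(res)
    } else {
      out$canonical[i] <- res$can
      logitCols[i, ] <- res$logits
    }
  }
  colnames(logitCols) <- paste0("logit_", seq_len(nt))
  out <- cbind(out, logitCols)
  if (identical(cfg$taskType, "classification")) {
    probs <- 1 / (1 + exp(-logitCols))
    colnames(probs) <- paste0("prob_", seq_len(nt))
    out <- cbind(out, probs)
  }
  out$error <- errs
  out
}

#' Export per-head attention matrices for one molecule
#'
#' Runs the forward pass and returns the row-stochastic attention matrices
#' of the requested stacked layer, labeled by channel: with 4 heads per
#' channel this yields 8 matrices (4 global, 4 local). The \code{[GLOBAL]}
#' node's row (the last row of each matrix) is the standard input for motif
#' attribution heatmaps.
#'
#' @param model a [MotifFuseModel-class] with the attention stack enabled.
#' @param smiles a single SMILES string.
#' @param layer layer index, or -1 for the last layer.
#' @return list with \code{motifKeys} and \code{global}/\code{local} lists
#'   of per-head N x N matrices.
#' @export
exportAttention <- function(model, smiles, layer = -1L) {
  if (!model@config$useGlTransformer)
    stop("attention export requires the attention stack to be enabled")
  nl <- model@config$attnLayers
  if (layer == -1L) layer <- nl
  if (layer < 1L || layer > nl)
    stop("layer index out of range (1..", nl, ")")
  entry <- .prepareEntry(smiles, model@vocab)
  fw <- .forwardOne(model, entry, withAttention = TRUE)
  att <- fw$attention[[layer]]
  list(motifKeys = entry$mg@motifKeys, globalIndex = entry$mg@globalIndex,
       global = att$global, local = att$local)
}

# parse + decompose + motif graph for one molecule
.prepareEntry <- function(smiles, vocab) {
  graph <- smilesToGraph(smiles)
  mg <- buildMotifGraph(graph, vocab = vocab)
  list(graph = graph, mg = mg)
}

#' Save / load a model
#'
#' Plain-text JSON serialization of the parameters, configuration and
#' vocabulary, so checkpoints survive across platforms.
#'
#' @param model a [MotifFuseModel-class].
#' @param path file path.
#' @return \code{loadModel} returns the restored model.
#' @export
saveModel <- function(model, path) {
  obj <- list(
    config = model@config,
    vocab = model@vocab@keys,
    params = lapply(model@params, function(m)
      list(dim = dim(m), data = as.numeric(m)))
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyVector = TRUE)
  cfg <- do.call(motifFuseConfig, obj$config[names(obj$config) %in%
                   names(formals(motifFuseConfig))])
  params <- lapply(obj$params, function(pm)
    matrix(pm$data, pm$dim[1L], pm$dim[2L]))
  vocab <- new("MotifVocabulary",
               keys = as.character(unlist(obj$vocab)))
  new("MotifFuseModel", params = params, config = cfg, vocab = vocab)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so library internals never perturb user-level reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the expression's value.
#' @export
withRNG <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
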