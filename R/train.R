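# Training: a tape-recorded forward pass equivalent to the inference path
# (the equivalence is asserted in the tests), reverse-mode gradients, and
# Adam. Classification minimizes binary cross-entropy with logits (missing
# labels masked out); regression minimizes mean squared error.

#' Training control parameters
#'
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param seed seed controlling shuffling (and nothing else).
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param verbose print a per-epoch line.
#' @return named list of control values.
#' @export
trainControl <- function(lr = 1e-4, batchSize = 256L, epochs = 100L,
                         seed = 0L, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, verbose = FALSE) {
  if (lr < 0) stop("learning rate must be nonnegative")
  if (batchSize < 1L) stop("batch size must be positive")
  if (epochs < 1L) stop("epochs must be positive")
  list(lr = lr, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), seed = as.integer(seed),
       beta1 = beta1, beta2 = beta2, epsilon = epsilon,
       verbose = isTRUE(verbose))
}

# ---- batched tape forward ------------------------------------------------

# assemble constant batch structures shared by every forward pass
.batchStructure <- function(entries) {
  counts <- vapply(entries, function(e) numAtoms(e$graph), integer(1))
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  atomRaw <- do.call(rbind, lapply(entries, function(e) e$graph@atomFeatures))
  molOf <- rep(seq_along(entries), counts)
  edges <- list(); bondRaw <- list(); revs <- list()
  eOff <- 0L
  for (i in seq_along(entries)) {
    g <- entries[[i]]$graph
    ne <- nrow(g@edges)
    if (ne > 0L) {
      edges[[i]] <- g@edges + offsets[i]
      bondRaw[[i]] <- g@bondFeatures
      revs[[i]] <- g@reverseIndex + eOff
      eOff <- eOff + ne
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(0), 0L, 2L)
  list(counts = counts, offsets = offsets, atomRaw = atomRaw,
       molOf = molOf, edges = edges,
       bondRaw = if (length(bondRaw)) do.call(rbind, bondRaw) else
         matrix(numeric(0), 0L, bondFeatureLength()),
       rev = if (length(revs)) unlist(revs) else integer(0))
}

# tape forward over a batch; returns list(tape, logits id)
.tapeForward <- function(model, entries, bs = .batchStructure(entries)) {
  cfg <- model@config
  d <- cfg$hiddenSize
  tape <- .tapeNew()
  pid <- lapply(model@params, function(x) NULL)
  for (nm in names(model@params))
    pid[[nm]] <- .tpParam(tape, model@params[[nm]], nm)

  nAtoms <- nrow(bs$atomRaw)
  a0 <- .tpConst(tape, bs$atomRaw)
  x <- .tpRelu(tape, .tpAdd(tape, .tpMM(tape, a0, pid$Watom), pid$batom))
  hv <- x
  ne <- nrow(bs$edges)
  if (ne > 0L) {
    src <- bs$edges[, 1L]; dst <- bs$edges[, 2L]
    eraw <- .tpConst(tape, cbind(bs$atomRaw[src, , drop = FALSE], bs$bondRaw))
    e0 <- .tpRelu(tape, .tpAdd(tape, .tpMM(tape, eraw, pid$Wbond), pid$bbond))
    he <- e0
    if (cfg$depth > 0L) for (k in seq_len(cfg$depth)) {
      sumIn <- .tpScatterSumRows(tape, he, dst, nAtoms)
      maxIn <- .tpGroupMaxRows(tape, he, dst, nAtoms)
      hv <- .tpAdd(tape, hv, .tpMul(tape, sumIn, maxIn))
      me <- .tpSub(tape, .tpGatherRows(tape, hv, src),
                   .tpGatherRows(tape, he, bs$rev))
      he <- .tpRelu(tape, .tpAdd(tape, .tpMM(tape, me, pid[[paste0("Wk_", k)]]),
                                 e0))
    }
    mv <- .tpMul(tape, .tpScatterSumRows(tape, he, dst, nAtoms),
                 .tpGroupMaxRows(tape, he, dst, nAtoms))
  } else {
    mv <- .tpConst(tape, matrix(0, nAtoms, d))
  }
  X <- .tpRelu(tape, .tpAdd(tape,
         .tpMM(tape, .tpAdd(tape, .tpAdd(tape, hv, mv), x), pid$Wcomm),
         pid$bcomm))

  B <- length(entries)
  if (identical(cfg$readout, "mean")) {
    M <- .tpScaleRows(tape, .tpScatterSumRows(tape, X, bs$molOf, B),
                      1 / bs$counts)
  } else {
    M <- .tpConcatCols(tape, list(
      .gruDirection(tape, pid, X, bs, forward = TRUE),
      .gruDirection(tape, pid, X, bs, forward = FALSE)))
    M <- .tpScaleRows(tape, M, 1 / bs$counts)
  }

  if (cfg$useGlTransformer) {
    mb <- .motifBatchStructure(entries, bs, cfg)
    embRows <- nrow(model@params$emb)
    norm <- if (cfg$perMotifNorm) mb$perMotifCounts else
      rep(bs$counts, mb$nMotifs)
    proj <- .tpRelu(tape, .tpAdd(tape,
      .tpScaleRows(tape, .tpMM(tape, .tpMMConstLeft(tape, mb$Fblock, X),
                               pid$WG), 1 / norm),
      pid$bG))
    ident <- .tpGatherRows(tape, pid$emb, mb$motifIndices)
    fusedMotifs <- .tpAdd(tape, proj, ident)
    globals <- .tpGatherRows(tape, pid$emb, rep(embRows, B))
    # interleave: each molecule's motif rows followed by its global row
    H <- .tpGatherRows(tape, .tpConcatRows(tape, list(fusedMotifs, globals)),
                       mb$interleave)
    for (l in seq_len(cfg$attnLayers))
      H <- .tpGlLayer(tape, pid, H, mb$masks, l, cfg)
    Hpool <- if (identical(cfg$pooling, "mean")) {
      .tpScaleRows(tape, .tpScatterSumRows(tape, H, mb$molOfRow, B),
                   1 / (mb$nMotifs + 1L))
    } else {
      .tpGatherRows(tape, H, mb$globalRows)
    }
    M <- .tpAdd(tape, M, .tpScaleScalar(tape, Hpool, pid$alpha))
  }
  logits <- .tpAdd(tape, .tpMM(tape, M, pid$Whead), pid$bhead)
  list(tape = tape, logits = logits)
}

# one direction of the batched recurrent readout; returns the per-molecule
# summed hidden states (B x d/2), caller divides by atom counts
.gruDirection <- function(tape, pid, X, bs, forward = TRUE) {
  dir <- if (forward) "f" else "b"
  w <- lapply(c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh"),
              function(s) pid[[paste0("gru_", dir, "_", s)]])
  names(w) <- c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh")
  B <- length(bs$counts)
  dh2 <- ncol(.tpVal(tape, w$Uz))
  h <- .tpConst(tape, matrix(0, B, dh2))
  S <- .tpConst(tape, matrix(0, B, dh2))
  for (t in seq_len(max(bs$counts))) {
    active <- which(bs$counts >= t)
    pos <- if (forward) t else bs$counts[active] - t + 1L
    rows <- bs$offsets[active] + pos
    xt <- .tpGatherRows(tape, X, rows)
    ha <- .tpGatherRows(tape, h, active)
    z <- .tpSigmoid(tape, .tpAdd(tape, .tpAdd(tape,
           .tpMM(tape, xt, w$Wz), .tpMM(tape, ha, w$Uz)), w$bz))
    r <- .tpSigmoid(tape, .tpAdd(tape, .tpAdd(tape,
           .tpMM(tape, xt, w$Wr), .tpMM(tape, ha, w$Ur)), w$br))
    hh <- .tpTanh(tape, .tpAdd(tape, .tpAdd(tape,
           .tpMM(tape, xt, w$Wh), .tpMM(tape, .tpMul(tape, r, ha), w$Uh)),
           w$bh))
    ones <- matrix(1, length(active), dh2)
    hnew <- .tpAdd(tape, .tpMul(tape, .tpSub(tape, .tpConst(tape, ones), z),
                                ha),
                   .tpMul(tape, z, hh))
    h <- .tpRowsReplace(tape, h, active, hnew)
    S <- .tpAdd(tape, S, .tpScatterSumRows(tape, hnew, active, B))
  }
  S
}

# Constant structures for batching the fusion + attention stack across
# molecules: a block-diagonal association matrix, the interleaving
# permutation (each molecule's motif rows then its global row), and
# block-diagonal channel masks. Cross-molecule score entries are forced to
# -Inf additively, which reproduces the per-molecule softmax exactly while
# keeping the within-block mask semantics (multiplicative as printed).
.motifBatchStructure <- function(entries, bs, cfg) {
  B <- length(entries)
  mgs <- lapply(entries, `[[`, "mg")
  nMotifs <- vapply(mgs, function(mg) mg@n, integer(1))
  Nrows <- nMotifs + 1L
  Ttot <- sum(Nrows)
  motOff <- cumsum(c(0L, nMotifs[-B]))
  rowOff <- cumsum(c(0L, Nrows[-B]))
  Fblock <- matrix(0, sum(nMotifs), nrow(bs$atomRaw))
  interleave <- integer(Ttot)
  molOfRow <- integer(Ttot)
  maskG <- matrix(0, Ttot, Ttot)
  maskL <- matrix(0, Ttot, Ttot)
  for (i in seq_len(B)) {
    mg <- mgs[[i]]
    Fblock[motOff[i] + seq_len(nMotifs[i]),
           bs$offsets[i] + seq_len(ncol(mg@F))] <- mg@F
    rows <- rowOff[i] + seq_len(Nrows[i])
    interleave[rows] <- c(motOff[i] + seq_len(nMotifs[i]),
                          sum(nMotifs) + i)
    molOfRow[rows] <- i
    m <- .attentionMasks(mg@A, mg@D, cfg)
    maskG[rows, rows] <- m$global
    maskL[rows, rows] <- m$local
  }
  sameBlock <- outer(molOfRow, molOfRow, "==")
  buildMask <- function(blockMask) {
    if (identical(cfg$maskMode, "multiplicative")) {
      mult <- blockMask
      add <- ifelse(sameBlock, 0, -Inf)
    } else if (identical(cfg$maskMode, "additive_neg_inf")) {
      mult <- 1 * sameBlock
      add <- ifelse(sameBlock & blockMask != 0, 0, -Inf)
    } else {
      mult <- 1 * sameBlock
      add <- ifelse(sameBlock, 0, -Inf)
    }
    list(mult = mult, add = add)
  }
  list(nMotifs = nMotifs, Fblock = Fblock, interleave = interleave,
       molOfRow = molOfRow, globalRows = cumsum(Nrows),
       motifIndices = unlist(lapply(mgs, function(mg) mg@motifIndices)),
       perMotifCounts = unlist(lapply(mgs, function(mg)
         pmax(rowSums(mg@F), 1))),
       masks = list(global = buildMask(maskG), local = buildMask(maskL)))
}

# one global-local attention layer on the tape
.tpGlLayer <- function(tape, pid, H, masks, l, cfg) {
  d <- cfg$hiddenSize
  half <- d %/% 2L
  Hg <- .tpSliceCols(tape, H, 1L, half)
  Hl <- .tpSliceCols(tape, H, half + 1L, d)
  outG <- .tpChannelAttention(tape, Hg, masks$global,
    pid[[paste0("attn", l, "_g_Wq")]], pid[[paste0("attn", l, "_g_Wk")]],
    pid[[paste0("attn", l, "_g_Wv")]], cfg$headsPerChannel)
  outL <- .tpChannelAttention(tape, Hl, masks$local,
    pid[[paste0("attn", l, "_l_Wq")]], pid[[paste0("attn", l, "_l_Wk")]],
    pid[[paste0("attn", l, "_l_Wv")]], cfg$headsPerChannel)
  .tpLayerNormRows(tape,
    .tpAdd(tape, H, .tpConcatCols(tape, list(outG, outL))),
    pid[[paste0("ln", l, "_gamma")]], pid[[paste0("ln", l, "_beta")]])
}

.tpChannelAttention <- function(tape, H, maskPair, wq, wk, wv, heads) {
  dc <- ncol(.tpVal(tape, H))
  hw <- dc %/% heads
  Q <- .tpMM(tape, H, wq); K <- .tpMM(tape, H, wk); V <- .tpMM(tape, H, wv)
  scale <- sqrt(dc)
  addConst <- if (any(is.infinite(maskPair$add)))
    .tpConst(tape, maskPair$add) else NULL
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * hw + 1L):(h * hw)
    s <- .tpMMT(tape, .tpSliceCols(tape, Q, cols[1L], cols[hw]),
                .tpSliceCols(tape, K, cols[1L], cols[hw]))
    s <- .tpMulConst(tape, s, maskPair$mult / scale)
    if (!is.null(addConst)) s <- .tpAdd(tape, s, addConst)
    P <- .tpSoftmaxRows(tape, s)
    outs[[h]] <- .tpMM(tape, P, .tpSliceCols(tape, V, cols[1L], cols[hw]))
  }
  .tpConcatCols(tape, outs)
}

# ---- optimizer -----------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, ctl) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- ctl$beta1 * state$m[[nm]] + (1 - ctl$beta1) * g
    state$v[[nm]] <- ctl$beta2 * state$v[[nm]] + (1 - ctl$beta2) * g^2
    mhat <- state$m[[nm]] / (1 - ctl$beta1^state$t)
    vhat <- state$v[[nm]] / (1 - ctl$beta2^state$t)
    params[[nm]] <- params[[nm]] - ctl$lr * mhat / (sqrt(vhat) + ctl$epsilon)
  }
  list(params = params, state = state)
}

# ---- metrics -------------------------------------------------------------

#' Root mean square error
#' @param observed,predicted numeric vectors.
#' @return RMSE (NA pairs dropped).
#' @export
rmseScore <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  sqrt(mean((observed[ok] - predicted[ok])^2))
}

#' Area under the ROC curve
#'
#' @param labels binary labels (0/1).
#' @param scores prediction scores (any monotone scale).
#' @return ROC-AUC; NA when only one class is present.
#' @export
rocAucScore <- function(labels, scores) {
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]; scores <- scores[ok]
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

# task metric over a label matrix: mean ROC-AUC over usable tasks, or RMSE
.taskMetric <- function(taskType, labels, preds) {
  if (identical(taskType, "classification")) {
    aucs <- vapply(seq_len(ncol(labels)), function(j)
      rocAucScore(labels[, j], preds[, j]), numeric(1))
    if (all(is.na(aucs)))
      stop("no task has both classes present; ROC-AUC undefined")
    if (anyNA(aucs))
      warning(sum(is.na(aucs)), " task(s) skipped: only one class present")
    mean(aucs, na.rm = TRUE)
  } else {
    rmseScore(as.numeric(labels), as.numeric(preds))
  }
}

# ---- training loop -------------------------------------------------------

.batchLoss <- function(model, entries, labels) {
  fw <- .tapeForward(model, entries)
  mask <- 1 * !is.na(labels)
  target <- labels
  target[is.na(target)] <- 0
  lossId <- if (identical(model@config$taskType, "classification"))
    .tpBceLogitsLoss(fw$tape, fw$logits, target, mask)
  else
    .tpMseLoss(fw$tape, fw$logits, target, mask)
  list(tape = fw$tape, lossId = lossId,
       loss = .tpVal(fw$tape, lossId)[1L, 1L])
}

# plain-forward predictions for a set of dataset indices
.predictEntries <- function(model, entries) {
  out <- vapply(entries, function(e) .forwardOne(model, e)$logits,
                numeric(model@config$nTargets))
  if (is.matrix(out)) t(out) else matrix(out, ncol = 1L)
}

#' Train a model
#'
#' Minimizes the task loss over the training indices with Adam, evaluates
#' the validation metric after every epoch, and returns the parameters of
#' the best validation epoch (highest ROC-AUC or lowest RMSE).
#'
#' @param model a freshly built or pre-trained [MotifFuseModel-class].
#' @param dataset a prepared dataset from [prepareDataset()].
#' @param trainIdx,valIdx integer indices into the dataset.
#' @param control a list from [trainControl()].
#' @return list with \code{model} (best checkpoint), \code{log} (per-epoch
#'   data.frame: epoch, trainLoss, valMetric), and \code{bestEpoch}.
#' @export
trainModel <- function(model, dataset, trainIdx, valIdx,
                       control = trainControl()) {
  if (length(trainIdx) == 0L) stop("empty training split")
  if (length(valIdx) == 0L) stop("empty validation split")
  cfg <- model@config
  classify <- identical(cfg$taskType, "classification")
  labels <- dataset$labels
  if (ncol(labels) != cfg$nTargets)
    stop("dataset has ", ncol(labels), " target(s) but the model expects ",
         cfg$nTargets)
  state <- .adamInit(model@params)
  log <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                    valMetric = numeric(0))
  best <- list(metric = if (classify) -Inf else Inf, params = model@params,
               epoch = 0L)
  withRNG(control$seed, {
    for (epoch in seq_len(control$epochs)) {
      idx <- sample(trainIdx)
      nb <- ceiling(length(idx) / control$batchSize)
      epochLoss <- 0
      for (b in seq_len(nb)) {
        take <- idx[((b - 1L) * control$batchSize + 1L):
                      min(b * control$batchSize, length(idx))]
        bl <- .batchLoss(model, dataset$entries[take],
                         labels[take, , drop = FALSE])
        if (!is.finite(bl$loss))
          stop("non-finite loss at epoch ", epoch, ", batch ", b,
               "; try a smaller learning rate")
        grads <- .tpBackward(bl$tape, bl$lossId)
        upd <- .adamStep(model@params, grads, state, control)
        model@params <- upd$params
        state <- upd$state
        epochLoss <- epochLoss + bl$loss * length(take)
      }
      epochLoss <- epochLoss / length(idx)
      valPred <- .predictEntries(model, dataset$entries[valIdx])
      # an undefined metric (e.g. a one-class validation split) must not
      # kill training; the epoch is logged as NA and never selected
      valMetric <- tryCatch(
        .taskMetric(cfg$taskType, labels[valIdx, , drop = FALSE], valPred),
        error = function(e) NA_real_)
      log[nrow(log) + 1L, ] <- list(epoch, epochLoss, valMetric)
      improved <- is.finite(valMetric) &&
        if (classify) valMetric > best$metric else valMetric < best$metric
      if (is.finite(valMetric) && improved)
        best <- list(metric = valMetric, params = model@params,
                     epoch = epoch)
      if (control$verbose)
        message(sprintf("epoch %3d  train loss %.5f  val %s %.4f",
                        epoch, epochLoss,
                        if (classify) "ROC-AUC" else "RMSE", valMetric))
    }
  })
  if (best$epoch == 0L) {
    warning("validation metric was undefined in every epoch; ",
            "returning the final parameters")
    best <- list(params = model@params, epoch = control$epochs)
  }
  model@params <- best$params
  list(model = model, log = log, bestEpoch = best$epoch)
}

#' Evaluate a model on a dataset split
#'
#' @param model a trained [MotifFuseModel-class].
#' @param dataset a prepared dataset from [prepareDataset()].
#' @param idx indices of the split to score.
#' @return the task metric: mean ROC-AUC over tasks with both classes
#'   present (classification) or RMSE (regression).
#' @export
evaluateModel <- function(model, dataset, idx = seq_along(dataset$entries)) {
  preds <- .predictEntries(model, dataset$entries[idx])
  .taskMetric(model@config$taskType,
              dataset$labels[idx, , drop = FALSE], preds)
}
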