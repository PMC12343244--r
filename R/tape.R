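# Minimal reverse-mode automatic differentiation on dense matrices.
# Internal machinery for training: the forward pass records a tape of matrix
# ops; .tpBackward sweeps it in reverse, accumulating gradients for nodes
# registered as parameters. Values are plain numeric matrices throughout.
# Correctness is pinned by finite-difference tests.

.tapeNew <- function() {
  tape <- new.env(parent = emptyenv())
  tape$vals <- vector("list", 256L)
  tape$back <- vector("list", 256L)
  tape$n <- 0L
  tape$paramIds <- integer(0)
  tape$paramNames <- character(0)
  tape
}

.tpPush <- function(tape, value, back = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$vals)) {
    length(tape$vals) <- 2L * length(tape$vals)
    length(tape$back) <- 2L * length(tape$back)
  }
  tape$vals[[n]] <- value
  if (!is.null(back)) tape$back[[n]] <- back
  tape$n <- n
  n
}

.tpVal <- function(tape, id) tape$vals[[id]]

.tpConst <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  .tpPush(tape, x)
}

.tpParam <- function(tape, x, name) {
  id <- .tpPush(tape, x)
  tape$paramIds <- c(tape$paramIds, id)
  tape$paramNames <- c(tape$paramNames, name)
  id
}

# C = A %*% B
.tpMM <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  .tpPush(tape, A %*% B, function(g, add) {
    add(a, g %*% t(B)); add(b, t(A) %*% g)
  })
}

# C = A %*% t(B)
.tpMMT <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  .tpPush(tape, A %*% t(B), function(g, add) {
    add(a, g %*% B); add(b, t(g) %*% A)
  })
}

# constant matrix times node
.tpMMConstLeft <- function(tape, M, b) {
  force(M); force(b)
  B <- tape$vals[[b]]
  .tpPush(tape, M %*% B, function(g, add) add(b, t(M) %*% g))
}

# elementwise add; a 1-row second operand broadcasts over rows
.tpAdd <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  if (nrow(B) == 1L && nrow(A) > 1L) {
    .tpPush(tape, sweep(A, 2L, B[1L, ], "+"), function(g, add) {
      add(a, g); add(b, matrix(colSums(g), 1L))
    })
  } else {
    .tpPush(tape, A + B, function(g, add) { add(a, g); add(b, g) })
  }
}

.tpSub <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  .tpPush(tape, A - B, function(g, add) { add(a, g); add(b, -g) })
}

# elementwise product of two same-shape nodes
.tpMul <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[a]]; B <- tape$vals[[b]]
  .tpPush(tape, A * B, function(g, add) { add(a, g * B); add(b, g * A) })
}

# elementwise product with a constant matrix / scalar
.tpMulConst <- function(tape, a, M) {
  force(a)
  A <- tape$vals[[a]]
  .tpPush(tape, A * M, function(g, add) add(a, g * M))
}

# per-row constant weights
.tpScaleRows <- function(tape, a, w) {
  force(a)
  A <- tape$vals[[a]]
  .tpPush(tape, A * w, function(g, add) add(a, g * w))
}

# scale by a learnable 1x1 scalar node
.tpScaleScalar <- function(tape, a, s) {
  force(a); force(s)
  A <- tape$vals[[a]]; S <- tape$vals[[s]][1L, 1L]
  .tpPush(tape, A * S, function(g, add) {
    add(a, g * S); add(s, matrix(sum(g * A), 1L, 1L))
  })
}

.tpRelu <- function(tape, a) {
  force(a)
  A <- tape$vals[[a]]
  mask <- A > 0
  .tpPush(tape, A * mask, function(g, add) add(a, g * mask))
}

.tpSigmoid <- function(tape, a) {
  force(a)
  S <- 1 / (1 + exp(-tape$vals[[a]]))
  .tpPush(tape, S, function(g, add) add(a, g * S * (1 - S)))
}

.tpTanh <- function(tape, a) {
  force(a)
  Th <- tanh(tape$vals[[a]])
  .tpPush(tape, Th, function(g, add) add(a, g * (1 - Th^2)))
}

# row-wise softmax; -Inf entries are legal and get weight 0
.tpSoftmaxRows <- function(tape, a) {
  force(a)
  A <- tape$vals[[a]]
  mx <- apply(A, 1L, max)
  E <- exp(A - mx)
  E[is.nan(E)] <- 0          # rows containing -Inf: exp(-Inf - -Inf)
  P <- E / rowSums(E)
  .tpPush(tape, P, function(g, add) {
    add(a, P * (g - rowSums(g * P)))
  })
}

# row-wise layer normalization with learnable affine (gamma, beta are 1 x d)
.tpLayerNormRows <- function(tape, a, gammaId, betaId, eps = 1e-5) {
  force(a); force(gammaId); force(betaId)
  A <- tape$vals[[a]]
  gam <- tape$vals[[gammaId]][1L, ]
  bet <- tape$vals[[betaId]][1L, ]
  d <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(sweep(xhat, 2L, gam, "*"), 2L, bet, "+")
  .tpPush(tape, Y, function(g, add) {
    gg <- sweep(g, 2L, gam, "*")
    add(a, inv * (gg - rowMeans(gg) - xhat * rowMeans(gg * xhat)))
    add(gammaId, matrix(colSums(g * xhat), 1L))
    add(betaId, matrix(colSums(g), 1L))
  })
}

.tpGatherRows <- function(tape, a, idx) {
  force(a)
  A <- tape$vals[[a]]
  nr <- nrow(A)
  .tpPush(tape, A[idx, , drop = FALSE], function(g, add) {
    G <- matrix(0, nr, ncol(g))
    rs <- rowsum(g, idx)
    G[as.integer(rownames(rs)), ] <- rs
    add(a, G)
  })
}

# sum rows of a into nOut groups given by idx (length nrow(a))
.tpScatterSumRows <- function(tape, a, idx, nOut) {
  force(a)
  A <- tape$vals[[a]]
  out <- matrix(0, nOut, ncol(A))
  if (nrow(A) > 0L) {
    rs <- rowsum(A, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  .tpPush(tape, out, function(g, add) add(a, g[idx, , drop = FALSE]))
}

# elementwise max over rows of a within groups; empty groups give zero rows
.tpGroupMaxRows <- function(tape, a, idx, nOut) {
  force(a)
  A <- tape$vals[[a]]
  d <- ncol(A)
  out <- matrix(0, nOut, d)
  amaxRow <- matrix(NA_integer_, nOut, d)
  byGroup <- split(seq_len(nrow(A)), idx)
  for (gname in names(byGroup)) {
    i <- as.integer(gname)
    rows <- byGroup[[gname]]
    sub <- A[rows, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    out[i, ] <- sub[cbind(w, seq_len(d))]
    amaxRow[i, ] <- rows[w]
  }
  .tpPush(tape, out, function(g, add) {
    G <- matrix(0, nrow(A), d)
    sel <- !is.na(amaxRow)
    G[cbind(amaxRow[sel], col(amaxRow)[sel])] <- g[sel]
    add(a, G)
  })
}

# replace rows idx of base with the rows node (same width); used by the GRU
.tpRowsReplace <- function(tape, base, idx, rowsNode) {
  force(base); force(rowsNode)
  B <- tape$vals[[base]]
  R <- tape$vals[[rowsNode]]
  out <- B
  out[idx, ] <- R
  .tpPush(tape, out, function(g, add) {
    gb <- g
    gb[idx, ] <- 0
    add(base, gb)
    add(rowsNode, g[idx, , drop = FALSE])
  })
}

.tpConcatCols <- function(tape, ids) {
  ids <- lapply(ids, identity)
  mats <- lapply(ids, function(i) tape$vals[[i]])
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  .tpPush(tape, do.call(cbind, mats), function(g, add) {
    for (k in seq_along(ids))
      add(ids[[k]], g[, starts[k]:ends[k], drop = FALSE])
  })
}

.tpSliceCols <- function(tape, a, from, to) {
  force(a)
  A <- tape$vals[[a]]
  nc <- ncol(A)
  .tpPush(tape, A[, from:to, drop = FALSE], function(g, add) {
    G <- matrix(0, nrow(A), nc)
    G[, from:to] <- g
    add(a, G)
  })
}

.tpConcatRows <- function(tape, ids) {
  ids <- lapply(ids, identity)
  mats <- lapply(ids, function(i) tape$vals[[i]])
  heights <- vapply(mats, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  .tpPush(tape, do.call(rbind, mats), function(g, add) {
    for (k in seq_along(ids))
      add(ids[[k]], g[starts[k]:ends[k], , drop = FALSE])
  })
}

.tpSliceRows <- function(tape, a, idx) .tpGatherRows(tape, a, idx)

# mean squared error over unmasked entries; returns a 1x1 node
.tpMseLoss <- function(tape, pred, target, mask) {
  force(pred)
  P <- tape$vals[[pred]]
  nEff <- sum(mask)
  diff <- (P - target) * mask
  .tpPush(tape, matrix(sum(diff^2) / nEff, 1L, 1L), function(g, add) {
    add(pred, g[1L, 1L] * 2 * diff / nEff)
  })
}

# binary cross-entropy with logits over unmasked entries; 1x1 node
.tpBceLogitsLoss <- function(tape, pred, target, mask) {
  force(pred)
  P <- tape$vals[[pred]]
  nEff <- sum(mask)
  y <- target
  y[mask == 0] <- 0
  softplus <- pmax(P, 0) + log1p(exp(-abs(P)))
  val <- sum(mask * (softplus - y * P)) / nEff
  .tpPush(tape, matrix(val, 1L, 1L), function(g, add) {
    s <- 1 / (1 + exp(-P))
    add(pred, g[1L, 1L] * mask * (s - y) / nEff)
  })
}

# reverse sweep from a scalar loss node; returns named parameter gradients
.tpBackward <- function(tape, lossId) {
  grads <- vector("list", tape$n)
  grads[[lossId]] <- matrix(1, 1L, 1L)
  add <- function(id, g) {
    if (is.null(grads[[id]])) grads[[id]] <<- g
    else grads[[id]] <<- grads[[id]] + g
  }
  for (id in seq.int(lossId, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    fn <- tape$back[[id]]
    if (!is.null(fn)) fn(g, add)
    if (id != lossId && !(id %in% tape$paramIds)) grads[id] <- list(NULL)
  }
  out <- grads[tape$paramIds]
  names(out) <- tape$paramNames
  out
}
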