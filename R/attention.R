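# Global-local masked attention over fused motif features. The feature
# dimension is split into two equal channels: the global channel's scores
# are modulated by the shortest-path distance matrix D, the local channel's
# by the adjacency matrix A. As printed in the source equations the masks
# multiply the raw scores before softmax (zero entries give score 0, not
# -Inf); an additive -Inf mode is available as a configuration alternative.

.layerNormRows <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  sweep(sweep(xc * inv, 2L, gamma, "*"), 2L, beta, "+")
}

.softmaxRows <- function(s) {
  mx <- apply(s, 1L, max)
  e <- exp(s - mx)
  e[is.nan(e)] <- 0
  e / rowSums(e)
}

#' Masked multi-head attention for one channel
#'
#' Scaled dot-product attention over the motif rows of one channel. Per
#' head: \code{scores = (Q K' * mask) / sqrt(d/2)} (multiplicative mask, as
#' printed), row-wise softmax, then the value projection; head outputs are
#' concatenated back to the channel width. \code{maskMode} selects how the
#' mask enters: \code{"multiplicative"} multiplies the raw scores,
#' \code{"additive_neg_inf"} sets scores at zero mask entries to \code{-Inf}
#' (so they receive no weight), \code{"none"} ignores the mask.
#'
#' @param H channel feature matrix (N x d/2), global node row included.
#' @param mask square N x N mask (distance or adjacency matrix).
#' @param Wq,Wk,Wv (d/2) x (d/2) projection weights; columns are split
#'   evenly across heads.
#' @param heads number of attention heads.
#' @param maskMode one of "multiplicative", "additive_neg_inf", "none".
#' @return list with \code{output} (N x d/2) and \code{attention} (list of
#'   per-head N x N row-stochastic matrices).
#' @export
channelAttention <- function(H, mask, Wq, Wk, Wv, heads = 1L,
                             maskMode = "multiplicative") {
  N <- nrow(H)
  dc <- ncol(H)
  if (!identical(dim(mask), c(N, N)))
    stop("mask must be square of the channel's row count")
  if (dc %% heads != 0L)
    stop("channel width must divide evenly across heads")
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  hw <- dc %/% heads
  out <- matrix(0, N, dc)
  attn <- vector("list", heads)
  scale <- sqrt(dc)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * hw + 1L):(h * hw)
    s <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])
    s <- switch(maskMode,
      multiplicative = (s * mask) / scale,
      additive_neg_inf = { s <- s / scale; s[mask == 0] <- -Inf; s },
      none = s / scale,
      stop("unknown maskMode '", maskMode, "'"))
    P <- .softmaxRows(s)
    out[, cols] <- P %*% V[, cols, drop = FALSE]
    attn[[h]] <- P
  }
  list(output = out, attention = attn)
}

# distance-matrix transform + ablation switches -> the two channel masks
.attentionMasks <- function(A, D, config) {
  N <- nrow(A)
  ones <- matrix(1, N, N)
  Dm <- if (isTRUE(config$useDistance)) {
    Dt <- D
    if (identical(config$distanceTransform, "reciprocal")) {
      Dt <- ifelse(D > 0, 1 / D, 0)
    }
    Dt
  } else ones
  Am <- if (isTRUE(config$useAdjacency)) {
    if (isTRUE(config$selfLoops)) A + diag(N) else A
  } else ones
  list(global = Dm, local = Am)
}

# weights of one stacked layer pulled out of the parameter list
.glLayerWeights <- function(params, layer) {
  pick <- function(ch, w) params[[paste0("attn", layer, "_", ch, "_", w)]]
  list(Wq_g = pick("g", "Wq"), Wk_g = pick("g", "Wk"), Wv_g = pick("g", "Wv"),
       Wq_l = pick("l", "Wq"), Wk_l = pick("l", "Wk"), Wv_l = pick("l", "Wv"),
       gamma = params[[paste0("ln", layer, "_gamma")]],
       beta = params[[paste0("ln", layer, "_beta")]])
}

#' One global-local attention layer
#'
#' Splits the fused motif features into a global half (first d/2 columns,
#' attended under the distance mask) and a local half (last d/2 columns,
#' attended under the adjacency mask), concatenates the two channel outputs,
#' and applies a residual connection with row-wise layer normalization.
#'
#' @param H fused motif feature matrix (N x d), global node row last.
#' @param A,D adjacency and distance matrices of size N x N (already
#'   transformed/ablated as desired, see [channelAttention()]).
#' @param weights list with \code{Wq_g,Wk_g,Wv_g,Wq_l,Wk_l,Wv_l} and the
#'   layer-norm affine \code{gamma,beta}.
#' @param heads heads per channel.
#' @param maskMode mask semantics, as in [channelAttention()].
#' @return list with \code{output} (N x d) and per-channel attention lists.
#' @export
glLayer <- function(H, A, D, weights, heads = 4L,
                    maskMode = "multiplicative") {
  d <- ncol(H)
  if (d %% 2L != 0L) stop("feature width must be even to split channels")
  half <- d %/% 2L
  Hg <- H[, seq_len(half), drop = FALSE]
  Hl <- H[, (half + 1L):d, drop = FALSE]
  g <- channelAttention(Hg, D, weights$Wq_g, weights$Wk_g, weights$Wv_g,
                        heads, maskMode)
  l <- channelAttention(Hl, A, weights$Wq_l, weights$Wk_l, weights$Wv_l,
                        heads, maskMode)
  out <- .layerNormRows(H + cbind(g$output, l$output),
                        weights$gamma[1L, ], weights$beta[1L, ])
  list(output = out, globalAttention = g$attention,
       localAttention = l$attention)
}

#' Combine molecule and refined motif representations
#'
#' The final molecular representation adds the refined motif signal --
#' pooled as the \code{[GLOBAL]} node's row (that node exists to aggregate
#' graph-level information; mean pooling over motif rows is available as an
#' alternative) -- to the encoder's molecule embedding through the learnable
#' scale \code{alpha}. With \code{alpha = 0} the molecule embedding passes
#' through unchanged.
#'
#' @param M molecule embedding vector (length d).
#' @param Hprime refined motif feature matrix (N x d).
#' @param alpha scalar scale.
#' @param globalIndex row of the \code{[GLOBAL]} node in \code{Hprime}.
#' @param pooling "global" (take the global row) or "mean" (average rows).
#' @return length-d final molecular representation.
#' @export
finalizeRepresentation <- function(M, Hprime, alpha,
                                   globalIndex = nrow(Hprime),
                                   pooling = "global") {
  pooled <- switch(pooling,
    global = Hprime[globalIndex, ],
    mean = colMeans(Hprime),
    stop("unknown pooling '", pooling, "'"))
  M + alpha * pooled
}
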