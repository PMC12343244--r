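# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain breadth-first searches,
# Floyd-Warshall, and per-node/per-edge loops.

# undirected bond list (src < dst) of a MolecularGraph
oracleBonds <- function(graph) {
  ed <- edgeList(graph)
  if (nrow(ed) == 0L) return(matrix(integer(0), 0L, 2L))
  b <- t(apply(ed, 1L, sort))
  unique(b)
}

# breadth-first reachability of `to` from `from` over a bond list
oracleReachable <- function(bonds, m, from, to) {
  seen <- logical(m)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v == to) return(TRUE)
    nb <- c(bonds[bonds[, 1L] == v, 2L], bonds[bonds[, 2L] == v, 1L])
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  seen[to]
}

# connected components over a bond list, by repeated BFS
oracleComponents <- function(bonds, m) {
  comp <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- c(bonds[bonds[, 1L] == v, 2L], bonds[bonds[, 2L] == v, 1L])
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# Reference decomposition: mark the broken-bond set (rule 1: acyclic bonds
# touching a ring system; rule 2: bonds at acyclic atoms with >= 3 heavy
# neighbors), then take connected components of what is left.
oracleDecompose <- function(graph) {
  m <- numAtoms(graph)
  bonds <- oracleBonds(graph)
  nb <- nrow(bonds)
  if (nb == 0L) return(lapply(seq_len(m), function(i) i))
  inRing <- vapply(seq_len(nb), function(b) {
    oracleReachable(bonds[-b, , drop = FALSE], m, bonds[b, 1L], bonds[b, 2L])
  }, logical(1))
  ringAtom <- logical(m)
  ringAtom[as.vector(bonds[inRing, , drop = FALSE])] <- TRUE
  deg <- tabulate(as.vector(bonds), nbins = m)
  branch <- deg >= 3L & !ringAtom
  broken <- vapply(seq_len(nb), function(b) {
    u <- bonds[b, 1L]; v <- bonds[b, 2L]
    (!inRing[b] && (ringAtom[u] || ringAtom[v])) || branch[u] || branch[v]
  }, logical(1))
  comp <- oracleComponents(bonds[!broken, , drop = FALSE], m)
  unname(split(seq_len(m), comp))
}

# canonical form of a partition for set comparison
partitionKey <- function(parts) {
  sorted <- lapply(parts, function(p) sort(as.integer(p)))
  paste(sort(vapply(sorted, paste, character(1), collapse = ",")),
        collapse = "|")
}

oracleFloydWarshall <- function(A) {
  n <- nrow(A)
  INF <- .Machine$integer.max / 4
  D <- matrix(INF, n, n)
  diag(D) <- 0
  D[A != 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D[D >= INF] <- n + 1
  D
}

# per-node/per-edge loop oracle for the message-passing encoder
# (input projections, K rounds, final communicate); returns atom embeddings
oracleEncoder <- function(params, graph, K) {
  relu <- function(v) pmax(v, 0)
  m <- numAtoms(graph)
  ed <- edgeList(graph)
  ne <- nrow(ed)
  A0 <- atomFeatures(graph)
  x <- lapply(seq_len(m), function(v)
    relu(as.numeric(A0[v, ] %*% params$Watom) + params$batom[1L, ]))
  e0 <- he <- vector("list", ne)
  for (e in seq_len(ne)) {
    raw <- c(A0[ed[e, 1L], ], bondFeatures(graph)[e, ])
    e0[[e]] <- relu(as.numeric(raw %*% params$Wbond) + params$bbond[1L, ])
    he[[e]] <- e0[[e]]
  }
  hv <- x
  agg <- function(he) {
    lapply(seq_len(m), function(v) {
      incoming <- which(ed[, 2L] == v)
      if (!length(incoming)) return(numeric(length(hv[[v]])))
      s <- numeric(length(he[[incoming[1L]]]))
      mx <- rep(-Inf, length(s))
      for (e in incoming) {
        s <- s + he[[e]]
        mx <- pmax(mx, he[[e]])
      }
      s * mx
    })
  }
  rev <- graph@reverseIndex
  if (K > 0L && ne > 0L) for (k in seq_len(K)) {
    mv <- agg(he)
    for (v in seq_len(m)) hv[[v]] <- hv[[v]] + mv[[v]]
    newHe <- vector("list", ne)
    for (e in seq_len(ne)) {
      me <- hv[[ed[e, 1L]]] - he[[rev[e]]]
      newHe[[e]] <- relu(as.numeric(me %*% params[[paste0("Wk_", k)]]) +
                           e0[[e]])
    }
    he <- newHe
  }
  mv <- if (ne > 0L) agg(he) else
    lapply(seq_len(m), function(v) numeric(length(hv[[v]])))
  out <- matrix(0, m, ncol(params$Wcomm))
  for (v in seq_len(m))
    out[v, ] <- relu(as.numeric((hv[[v]] + mv[[v]] + x[[v]]) %*%
                                  params$Wcomm) + params$bcomm[1L, ])
  out
}

# two-loop scaled dot-product attention oracle for one channel
oracleChannelAttention <- function(H, mask, Wq, Wk, Wv, heads = 1L,
                                   maskMode = "multiplicative") {
  N <- nrow(H); dc <- ncol(H); hw <- dc / heads
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  out <- matrix(0, N, dc)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * hw + 1L):(h * hw)
    for (i in seq_len(N)) {
      scores <- numeric(N)
      for (j in seq_len(N)) {
        s <- sum(Q[i, cols] * K[j, cols])
        scores[j] <- switch(maskMode,
          multiplicative = s * mask[i, j] / sqrt(dc),
          additive_neg_inf = if (mask[i, j] == 0) -Inf else s / sqrt(dc),
          none = s / sqrt(dc))
      }
      w <- exp(scores - max(scores))
      w[is.nan(w)] <- 0
      w <- w / sum(w)
      for (j in seq_len(N))
        out[i, cols] <- out[i, cols] + w[j] * V[j, cols]
    }
  }
  out
}
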