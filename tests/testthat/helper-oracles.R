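# Independent brute-force oracles. These deliberately use different
# algorithms (and where possible different library code paths) from the
# implementations they check.

# Interval-union oracle: repeatedly merge any two windows whose gap is at
# most max_gap until a fixed point, by pairwise scanning (quadratic).
oracle_interval_union <- function(pos, flank = 500000, max_gap = 1) {
  iv <- cbind(pmax(1, pos - flank), pos + flank)
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= nrow(iv) && !merged) {
      j <- i + 1
      while (j <= nrow(iv)) {
        gap <- max(iv[i, 1], iv[j, 1]) - min(iv[i, 2], iv[j, 2])
        if (gap <= max_gap) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
        j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}

# Connected-components oracle by breadth-first search over an edge list.
oracle_components <- function(n, edges) {
  comp <- rep(NA_integer_, n)
  cid <- 0L
  adj <- vector("list", n)
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# Carrier oracle: a leaf carries the mutation iff its root-ward ancestor
# path passes through the mutated node.
oracle_carriers <- function(gen, node) {
  hits <- character(0)
  for (leaf in seq_len(gen$n_leaves)) {
    v <- leaf
    found <- FALSE
    while (v != 0L) {
      if (v == node) { found <- TRUE; break }
      v <- gen$parent[v]
    }
    if (found) hits <- c(hits, gen$labels[leaf])
  }
  hits
}

# MRCA oracle by ancestor-path intersection: the common ancestor of all
# known carriers with the smallest node time.
oracle_mrca <- function(gen, labels) {
  paths <- lapply(match(labels, gen$labels), function(leaf) {
    v <- leaf
    path <- integer(0)
    while (v != 0L) {
      path <- c(path, v)
      v <- gen$parent[v]
    }
    path
  })
  common <- Reduce(intersect, paths)
  common[which.min(gen$time[common])]
}

# Central two-sided Fisher p computed from first principles with lchoose
# (no dhyper), matching the "sum of table probabilities <= observed" rule.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) -
    lchoose(m + n2, k)
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
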