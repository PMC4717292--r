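# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# direct summation of binomial terms for the upper-tail probability
direct_cbd <- function(x, n, f) {
  if (x <= 0) return(1)
  y <- x:n
  sum(choose(n, y) * f^y * (1 - f)^(n - y))
}

# rank-then-average quantile normalization
qn_oracle <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) target[rank(col, ties.method = "first")])
  dimnames(out) <- dimnames(m)
  out
}

# all-pairs top-k correlation network with significance threshold
grvn_oracle <- function(mat, neighborhood, alpha) {
  genes <- sort(rownames(mat))
  n <- ncol(mat)
  edges <- character()
  for (g in genes) {
    r <- sapply(setdiff(genes, g), function(h)
      cor(mat[g, ], mat[h, ]))
    ord <- order(-r, names(r))
    top <- names(r)[ord][seq_len(min(neighborhood, length(r)))]
    for (h in top) {
      rv <- r[[h]]
      p <- if (abs(rv) >= 1 - 1e-15) 0 else {
        t <- abs(rv) * sqrt((n - 2) / (1 - rv^2))
        2 * pt(t, df = n - 2, lower.tail = FALSE)
      }
      if (p < alpha) edges <- c(edges, paste(min(g, h), max(g, h)))
    }
  }
  sort(unique(edges))
}

# union-find connected components over an edge list
components_oracle <- function(edges_a, edges_b) {
  nodes <- sort(unique(c(edges_a, edges_b)))
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  split(nodes, vapply(nodes, find, ""))
}

# exhaustive enumeration of the degree-preserving null for a small
# reference PPI set with single-label proteins: every perfect matching of
# the pooled 2m endpoint stubs, all equally likely
loi_enumeration_oracle <- function(pa, pb, labels) {
  stubs <- labels[c(pa, pb)]
  matchings <- all_matchings(seq_along(stubs))
  key_of <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
  count_keys <- function(mt) {
    tb <- table(key_of(stubs[mt[, 1]], stubs[mt[, 2]]))
    tb
  }
  all_keys <- sort(unique(unlist(lapply(matchings, function(mt)
    names(count_keys(mt))))))
  counts <- t(sapply(matchings, function(mt) {
    tb <- count_keys(mt)
    v <- setNames(as.numeric(tb[all_keys]), all_keys)
    v[is.na(v)] <- 0
    v
  }))
  obs_tb <- table(key_of(labels[pa], labels[pb]))
  obs <- setNames(as.numeric(obs_tb[all_keys]), all_keys)
  obs[is.na(obs)] <- 0
  list(mean = colMeans(counts),
       sd = apply(counts, 2, function(v) sqrt(mean((v - mean(v))^2))),
       observed = obs)
}

# all perfect matchings of an even-sized index set, as lists of 2-column
# matrices
all_matchings <- function(idx) {
  if (!length(idx)) return(list(matrix(integer(), 0, 2)))
  first <- idx[1]
  out <- list()
  for (j in idx[-1]) {
    rest <- setdiff(idx, c(first, j))
    for (sub in all_matchings(rest))
      out[[length(out) + 1L]] <- rbind(c(first, j), sub)
  }
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small world used by several files; cached per session
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_world(world_config(seed = 42))
    cache
  }
})

# best-Jaccard matching of recovered complexes to planted ones
complex_jaccards <- function(planted, recovered) {
  vapply(planted, function(tc) {
    if (!length(recovered)) return(0)
    max(vapply(recovered, function(rc) {
      a <- tc$members
      b <- rc$nodes$gene
      length(intersect(a, b)) / length(union(a, b))
    }, 0))
  }, 0)
}
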