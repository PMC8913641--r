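# Independent brute-force oracles for shortest-path centralities.
# Distances come from a hand-rolled BFS; shortest paths are enumerated
# explicitly (depth-pruned DFS) and dependencies accumulated per path,
# so none of this shares code with the package implementation.

oracle_metrics <- function(adj) {
  n <- nrow(adj)
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ]))
  bfs <- function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    q <- s
    while (length(q) > 0) {
      v <- q[1L]
      q <- q[-1L]
      for (u in nbr[[v]]) {
        if (!is.finite(d[u])) {
          d[u] <- d[v] + 1
          q <- c(q, u)
        }
      }
    }
    d
  }
  D <- t(vapply(seq_len(n), bfs, numeric(n)))
  ndc <- vapply(nbr, length, 1L)
  ncc <- vapply(seq_len(n), function(v) {
    dd <- D[v, ]
    dd <- dd[is.finite(dd) & dd > 0]
    if (length(dd) == 0) 0 else 1 / mean(dd)
  }, 1)
  nbc_raw <- rep(0, n)
  ebc <- matrix(0, n, n)
  for (s in seq_len(n - 1L)) {
    for (t in seq(s + 1L, n)) {
      if (!is.finite(D[s, t])) next
      dtarget <- D[s, t]
      paths <- list()
      rec <- function(path) {
        v <- path[length(path)]
        if (v == t) {
          paths[[length(paths) + 1L]] <<- path
          return(invisible())
        }
        for (u in nbr[[v]]) {
          # extend only along prefixes of shortest paths
          if (length(path) + D[u, t] == dtarget) rec(c(path, u))
        }
      }
      rec(s)
      nsp <- length(paths)
      for (pp in paths) {
        if (length(pp) > 2) {
          mid <- pp[seq(2L, length(pp) - 1L)]
          nbc_raw[mid] <- nbc_raw[mid] + 1 / nsp
        }
        for (e in seq_len(length(pp) - 1L)) {
          a <- min(pp[e], pp[e + 1L])
          b <- max(pp[e], pp[e + 1L])
          ebc[a, b] <- ebc[a, b] + 1 / nsp
        }
      }
    }
  }
  nbc <- if (n > 2) nbc_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  list(D = D, ndc = ndc, ncc = ncc, nbc = nbc, ebc = ebc)
}

# random symmetric adjacency matrix with sorted node names
random_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(stats::runif(n * n) < p, n, n)
    a[lower.tri(a, diag = TRUE)] <- FALSE
    a <- a | t(a)
    dimnames(a) <- list(sprintf("t%02d", seq_len(n)),
                        sprintf("t%02d", seq_len(n)))
    a
  })
}

# signed_network from an adjacency matrix (r drawn in [-1,1] to exercise
# the attribute plumbing; metrics must ignore the weights by default)
adjacency_to_network <- function(adj, seed = 1) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  rs <- withr::with_seed(seed, stats::runif(nrow(idx), -1, 1))
  rs[rs == 0] <- 0.5
  edges <- data.frame(source = rownames(adj)[idx[, 1L]],
                      target = colnames(adj)[idx[, 2L]],
                      r = rs, stringsAsFactors = FALSE)
  signed_network(edges, nodes = rownames(adj))
}

# small named helpers used across test files
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

ring_network <- function(n) {
  nm <- sprintf("n%02d", seq_len(n))
  signed_network(data.frame(source = nm, target = nm[c(seq(2, n), 1L)]))
}

complete_network <- function(n) {
  nm <- sprintf("n%02d", seq_len(n))
  pr <- t(utils::combn(nm, 2))
  signed_network(data.frame(source = pr[, 1L], target = pr[, 2L]))
}

star_network <- function(n_leaves) {
  leaves <- sprintf("leaf%02d", seq_len(n_leaves))
  signed_network(data.frame(source = rep("hub", n_leaves), target = leaves))
}
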