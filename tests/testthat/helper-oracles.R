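# Independent brute-force oracles for graph metrics, used on tiny graphs.
# They avoid igraph entirely: BFS distances, exhaustive shortest-path
# enumeration for betweenness, and direct neighbourhood counting for
# clustering.

bruteDistances <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] > 0)
        newv <- nb[!is.finite(dist[s, nb])]
        newv <- setdiff(newv, s)
        dist[s, newv] <- d
        nxt <- c(nxt, newv)
      }
      frontier <- unique(nxt)
    }
  }
  dist
}

enumShortestPaths <- function(adj, s, t, dist) {
  if (s == t) return(list(s))
  out <- list()
  for (v in which(adj[s, ] > 0)) {
    if (is.finite(dist[v, t]) && dist[v, t] == dist[s, t] - 1) {
      for (p in enumShortestPaths(adj, v, t, dist))
        out <- c(out, list(c(s, p)))
    }
  }
  out
}

bruteBetweenness <- function(adj, normalized = TRUE) {
  n <- nrow(adj)
  dist <- bruteDistances(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    if (!is.finite(dist[s, t])) next
    paths <- enumShortestPaths(adj, s, t, dist)
    counts <- numeric(n)
    for (p in paths) {
      inter <- setdiff(p, c(s, t))
      counts[inter] <- counts[inter] + 1
    }
    btw <- btw + counts / length(paths)
  }
  if (normalized) btw / ((n - 1) * (n - 2) / 2) else btw
}

bruteClustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb] > 0) / (k * (k - 1))
  }, numeric(1))
}

brutePathLength <- function(adj) {
  dist <- bruteDistances(adj)
  vapply(seq_len(nrow(adj)), function(i) {
    di <- dist[i, -i]
    di <- di[is.finite(di)]
    if (length(di)) mean(di) else NA_real_
  }, numeric(1))
}

# Benjamini-Hochberg step-up by direct enumeration of the definition:
# find the largest k with p_(k) <= k/m * alpha and reject p-values up to it.
bruteBHReject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) k <- i
  rej <- logical(m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# r-domain ConnectivityMatrix from a plain symmetric weight matrix
connFromWeights <- function(w, n = 100, labels = NULL) {
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(w)))
  diag(w) <- 0
  connectivityMatrix(w, domain = "r", nTimepoints = n, labels = labels)
}

# undirected binary adjacency from a ThresholdedNetwork, in label order
adjacencyOf <- function(net) {
  g <- netGraph(net)
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  (a > 0) + 0
}

# tiny two-group synthetic connectivity dataset with an optional planted
# block delta, used in NBS tests
makeTwoGroups <- function(atlas, nPerGroup, nTimepoints, seed,
                          delta = NULL) {
  specA <- communitySpec(atlas)
  specB <- if (is.null(delta)) specA else
    communitySpec(atlas, groupEffects = list(delta))
  list(
    A = lapply(generateGroupTimeseries(atlas, specA, nPerGroup,
                                       nTimepoints, seed = seed),
               correlationMatrix),
    B = lapply(generateGroupTimeseries(atlas, specB, nPerGroup,
                                       nTimepoints, seed = seed + 1000L),
               correlationMatrix))
}
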