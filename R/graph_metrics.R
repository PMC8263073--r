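#' Threshold a connectivity matrix to a target mean degree
#'
#' Retains exactly `floor(R * k / 2)` edges with the largest weights, so
#' that each node has on average k connections (for a 72-region matrix at
#' k = 10 this keeps the strongest 360 edges). Ties at the cutoff are
#' broken deterministically by lexicographic (i, j) node order. Weights
#' are preserved on the retained edges.
#'
#' @param mat r-domain [ConnectivityMatrix-class] (positive weights).
#' @param k target mean degree.
#' @return A [ThresholdedNetwork-class].
#' @export
thresholdToDensity <- function(mat, k) {
  stopifnot(is(mat, "ConnectivityMatrix"))
  w <- connWeights(mat)
  R <- nrow(w)
  m <- floor(R * k / 2)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[ut]
  pos <- wt > 0
  if (sum(pos) < m)
    stop("only ", sum(pos), " positive edges available; maximum achievable ",
         "mean degree is ", format(2 * sum(pos) / R, digits = 4))
  ord <- order(-wt, ut[, 1], ut[, 2])[seq_len(m)]
  edges <- data.frame(from = regionLabels(mat)[ut[ord, 1]],
                      to = regionLabels(mat)[ut[ord, 2]],
                      weight = wt[ord])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = regionLabels(mat))
  new("ThresholdedNetwork", graph = g, k = k, m = as.integer(m),
      labels = regionLabels(mat))
}

#' Number of connected components
#'
#' @param net a [ThresholdedNetwork-class].
#' @return integer component count.
#' @export
countComponents <- function(net) {
  stopifnot(is(net, "ThresholdedNetwork"))
  igraph::components(netGraph(net))$no
}

#' Global small-world metrics with random-network normalization
#'
#' Computes the binary global clustering coefficient C (mean of local
#' clustering coefficients; nodes of degree < 2 contribute 0) and the
#' characteristic path length L (mean shortest-path hop count over all
#' connected ordered node pairs), then normalizes both against the mean of
#' `nNull` uniformly random graphs with the same number of nodes and edges
#' (Erdos-Renyi G(n, m)): gamma = C / C_rand, lambda = L / L_rand, and the
#' small-world index sigma = gamma / lambda. Disconnected null draws are
#' resampled (the count is reported); if the input graph itself is
#' disconnected, L is computed on its largest component and flagged.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param nNull number of random null networks (default 1000).
#' @param seed RNG seed for the null ensemble.
#' @param nullModel `"gnm"` (default) for uniform random graphs with
#'   matched node and edge counts, or `"rewire"` for degree-preserving
#'   edge rewiring of the input graph.
#' @return list with C, L, Crand, Lrand, gamma, lambda, sigma,
#'   nComponents, nNull, nResampled and connectedInput.
#' @export
globalMetrics <- function(net, nNull = 1000, seed = 1L,
                          nullModel = c("gnm", "rewire")) {
  stopifnot(is(net, "ThresholdedNetwork"))
  if (nNull < 1) stop("'nNull' must be at least 1")
  nullModel <- match.arg(nullModel)
  g <- netGraph(net)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  comp <- igraph::components(g)
  connected <- comp$no == 1
  C <- binaryClustering(g)
  L <- hopPathLength(if (connected) g else largestComponent(g, comp))
  nResampled <- 0L
  stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nNull), function(i) {
      repeat {
        gn <- if (nullModel == "gnm") igraph::sample_gnm(n, m)
              else igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
        if (igraph::is_connected(gn)) break
        nResampled <<- nResampled + 1L
      }
      c(binaryClustering(gn), hopPathLength(gn))
    }, numeric(2))
  })
  Crand <- mean(stats[1, ]); Lrand <- mean(stats[2, ])
  gamma <- C / Crand; lambda <- L / Lrand
  list(C = C, L = L, Crand = Crand, Lrand = Lrand,
       gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       nComponents = comp$no, nNull = nNull, nResampled = nResampled,
       connectedInput = connected)
}

binaryClustering <- function(g) {
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

# mean shortest-path hop count over ordered pairs of distinct nodes
hopPathLength <- function(g) {
  d <- igraph::distances(g, weights = NA)
  mean(d[row(d) != col(d)])
}

largestComponent <- function(g, comp = igraph::components(g)) {
  igraph::induced_subgraph(g, which(comp$membership ==
                                      which.max(comp$csize)))
}

#' Per-node network metrics
#'
#' Degree (number of connections), strength (sum of incident edge
#' weights), binary local clustering coefficient, average shortest-path
#' hop distance to all reachable nodes, and shortest-path betweenness
#' centrality (binary, normalized). All metrics except strength are
#' computed on the binarized graph.
#'
#' @param net a [ThresholdedNetwork-class].
#' @return data.frame with one row per node: region, degree, strength,
#'   clustering, pathLength, betweenness.
#' @export
nodeMetrics <- function(net) {
  stopifnot(is(net, "ThresholdedNetwork"))
  g <- netGraph(net)
  d <- igraph::distances(g, weights = NA)
  pl <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di)) mean(di) else NA_real_
  }, numeric(1))
  data.frame(
    region = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    strength = igraph::strength(g),
    clustering = igraph::transitivity(g, type = "localundirected",
                                      isolates = "zero"),
    pathLength = pl,
    betweenness = igraph::betweenness(g, weights = NA, normalized = TRUE),
    row.names = NULL)
}

#' Composite hub score
#'
#' Flags nodes that combine an above-average number of connections, high
#' betweenness centrality and a short average path length. The score is
#' the equal-weight mean of the within-network standard (z) scores of
#' degree, betweenness and negated average path length; higher is more
#' hub-like. A metric with zero variance across nodes contributes 0 (with
#' a warning). The formula is recorded in the `"formula"` attribute so
#' alternative composites are comparable.
#'
#' @param table a node metrics data.frame from [nodeMetrics()].
#' @return named numeric vector of hub scores.
#' @export
hubScores <- function(table) {
  stopifnot(all(c("region", "degree", "betweenness", "pathLength") %in%
                  names(table)))
  zscore <- function(x, nm) {
    if (any(!is.finite(x)))
      stop("non-finite ", nm, " (disconnected node?); hub scores need a ",
           "connected network")
    s <- stats::sd(x)
    # guard against floating-point spread in analytically equal metrics
    if (s <= sqrt(.Machine$double.eps) * max(1, abs(mean(x)))) {
      warning("zero variance in ", nm, "; component contributes 0")
      rep(0, length(x))
    } else (x - mean(x)) / s
  }
  sc <- (zscore(table$degree, "degree") +
           zscore(table$betweenness, "betweenness") +
           zscore(-table$pathLength, "pathLength")) / 3
  names(sc) <- table$region
  attr(sc, "formula") <-
    "mean(z(degree), z(betweenness), z(-pathLength))"
  sc
}

#' Ring lattice and edge-rewired benchmark graphs
#'
#' `ringLattice` builds the circulant graph in which every node connects
#' to its `k / 2` nearest neighbours on each side (the regular,
#' high-clustering end of the small-world spectrum). `rewireEdges`
#' rewires each edge with probability `p` (preserving the edge count),
#' moving the graph toward the random end; at small p this produces the
#' small-world regime.
#'
#' @param n number of nodes; @param k even mean degree.
#' @param graph an igraph object; @param p per-edge rewiring probability;
#' @param seed RNG seed.
#' @return an igraph object.
#' @export
ringLattice <- function(n, k) {
  if (k %% 2 != 0) stop("'k' must be even")
  if (k >= n) stop("'k' must be below n")
  from <- rep(seq_len(n), k / 2)
  shift <- rep(seq_len(k / 2), each = n)
  to <- ((from - 1 + shift) %% n) + 1
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::V(g)$name <- paste0("R", seq_len(n))
  g
}

#' @rdname ringLattice
#' @export
rewireEdges <- function(graph, p, seed = 1L) {
  withr::with_seed(as.integer(seed),
    igraph::rewire(graph, igraph::each_edge(p = p, loops = FALSE,
                                            multiple = FALSE)))
}

#' Export a network for force-based visualization
#'
#' Writes GraphML or GEXF with node attributes (hemisphere, functional
#' group, community, strength, hub score — whichever are supplied) and
#' the edge weight, ready for force-layout tools.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param path output file; @param format `"graphml"` or `"gexf"`.
#' @param nodeAttrs optional data.frame of per-node attributes with a
#'   `region` column matching the network's labels.
#' @return the path, invisibly.
#' @export
exportGraph <- function(net, path, format = c("graphml", "gexf"),
                        nodeAttrs = NULL) {
  format <- match.arg(format)
  g <- netGraph(net)
  if (!is.null(nodeAttrs)) {
    stopifnot("region" %in% names(nodeAttrs))
    idx <- match(igraph::V(g)$name, nodeAttrs$region)
    for (nm in setdiff(names(nodeAttrs), "region"))
      g <- igraph::set_vertex_attr(g, nm, value = nodeAttrs[[nm]][idx])
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    writeGexf(g, path)
  }
  invisible(path)
}

# minimal GEXF 1.2 serializer (igraph has no GEXF writer)
writeGexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  attrs <- setdiff(igraph::vertex_attr_names(g), "name")
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
             '<graph defaultedgetype="undirected">')
  if (length(attrs)) {
    lines <- c(lines, '<attributes class="node">',
               sprintf('<attribute id="%d" title="%s" type="string"/>',
                       seq_along(attrs) - 1L, esc(attrs)),
               '</attributes>')
  }
  lines <- c(lines, "<nodes>")
  for (i in seq_len(igraph::vcount(g))) {
    nm <- esc(igraph::V(g)$name[i])
    if (length(attrs)) {
      vals <- vapply(attrs, function(a)
        esc(igraph::vertex_attr(g, a)[i]), character(1))
      lines <- c(lines,
                 sprintf('<node id="%s" label="%s"><attvalues>%s</attvalues></node>',
                         nm, nm,
                         paste0(sprintf('<attvalue for="%d" value="%s"/>',
                                        seq_along(attrs) - 1L, vals),
                                collapse = "")))
    } else {
      lines <- c(lines, sprintf('<node id="%s" label="%s"/>', nm, nm))
    }
  }
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  lines <- c(lines, "</nodes>", "<edges>",
             sprintf('<edge id="%d" source="%s" target="%s" weight="%s"/>',
                     seq_len(nrow(el)) - 1L, esc(el[, 1]), esc(el[, 2]),
                     format(w, digits = 8)),
             "</edges>", "</graph>", "</gexf>")
  writeLines(lines, path)
}
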