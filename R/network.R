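#' Build a co-occurrence / co-exclusion network from an abundance table
#'
#' Features present (abundance > 0) in at least `prevalence_min` of the
#' samples enter the graph. Edges are Spearman correlations of abundance
#' across samples, Benjamini-Hochberg adjusted over all tested pairs; a pair
#' is connected when `|rho| >= rho_min` and `q <= q_max`. Positive edges are
#' co-occurrence, negative ones co-exclusion.
#'
#' @param table an [abundance_table()] with >= 5 samples
#' @param rho_min minimum absolute Spearman correlation (default 0.6)
#' @param q_max FDR cut on edges (default 0.05)
#' @param prevalence_min minimum fraction of samples a feature must be
#'   present in (default 0.2)
#' @return object of class `interaction_network`: list with `nodes`
#'   (character) and `edges` (data.frame u, v, rho, q, sign)
#' @export
build_network <- function(table, rho_min = 0.6, q_max = 0.05,
                          prevalence_min = 0.2) {
  stopifnot(inherits(table, "abundance_table"))
  n <- length(table$sample_ids)
  if (n < 5L) stop("need >= 5 samples for a meaningful correlation network")
  prevalence <- colMeans(table$values > 0)
  nodes <- table$feature_ids[prevalence >= prevalence_min]
  empty <- data.frame(u = character(), v = character(), rho = numeric(),
                      q = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  if (length(nodes) < 2L)
    return(structure(list(nodes = nodes, edges = empty),
                     class = "interaction_network"))
  X <- table$values[, nodes, drop = FALSE]
  pairs <- combn(nodes, 2)
  rho <- numeric(ncol(pairs))
  p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    x <- X[, pairs[1, j]]; y <- X[, pairs[2, j]]
    if (sd(x) == 0 || sd(y) == 0) { rho[j] <- 0; p[j] <- 1; next }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    rho[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  q <- p.adjust(p, method = "BH")
  keep <- abs(rho) >= rho_min & q <= q_max
  edges <- if (any(keep)) {
    data.frame(u = pairs[1, keep], v = pairs[2, keep], rho = rho[keep],
               q = q[keep],
               sign = ifelse(rho[keep] > 0, "co-occurrence", "co-exclusion"),
               stringsAsFactors = FALSE)
  } else empty
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Topology statistics of an interaction network
#'
#' Reports node count, number of isolated islands (connected components),
#' density `2E / (N (N - 1))`, unweighted diameter and radius within the
#' largest component (0 for an edgeless graph), and Freeman degree
#' centralization `sum(d_max - d_i) / ((N - 1)(N - 2))` over the whole graph
#' (0 when N < 3).
#'
#' @param net an `interaction_network`
#' @return data.frame with n_nodes, n_islands, density, diameter, radius,
#'   centralization
#' @export
network_topology <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  n <- length(net$nodes)
  if (n == 0L)
    return(data.frame(n_nodes = 0, n_islands = 0, density = 0, diameter = 0,
                      radius = 0, centralization = 0))
  g <- igraph::graph_from_data_frame(net$edges[, c("u", "v"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  comps <- igraph::components(g)
  density <- if (n >= 2) 2 * nrow(net$edges) / (n * (n - 1)) else 0
  if (nrow(net$edges) == 0L) {
    diameter <- 0; radius <- 0
  } else {
    big <- which.max(comps$csize)
    sub <- igraph::induced_subgraph(g, which(comps$membership == big))
    ecc <- igraph::eccentricity(sub)
    diameter <- max(ecc); radius <- min(ecc)
  }
  centralization <- if (n < 3) 0 else {
    deg <- igraph::degree(g)
    sum(max(deg) - deg) / ((n - 1) * (n - 2))
  }
  data.frame(n_nodes = n, n_islands = unname(comps$no), density = density,
             diameter = unname(diameter), radius = unname(radius),
             centralization = centralization)
}
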