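# eccDriver steps 2-5: degree centrality in the reference PPI network,
# depth-2 DEG-based local networks, weighted semi-local centrality
# C_WL(v) = N(v) + alpha * Q(v), and the EDG impact score
# EGIS(v) = (K(v) + 1) * (C_WL(v) + 1).

#' Build an undirected PPI graph
#'
#' @param edges A normalized edge data.frame from [read_ppi()] /
#'   [ppi_edges()] (columns `gene_a`, `gene_b`, `confidence`).
#' @param nodes Optional extra node ids to retain even when isolated.
#' @return An undirected [igraph::igraph] with a `confidence` edge
#'   attribute; no self-loops or multi-edges.
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "confidence")], directed = FALSE,
    vertices = if (is.null(nodes)) NULL else
      data.frame(name = sort(unique(c(nodes, edges$gene_a, edges$gene_b))),
                 stringsAsFactors = FALSE))
  stopifnot(igraph::is_simple(g))
  g
}

#' Degree centrality K(v) in the reference PPI network
#'
#' @param ppi An igraph from [ppi_graph()].
#' @param gene Gene id; must be a node of the graph (genes not covered by
#'   the PPI network are removed before ranking).
#' @return Integer degree.
#' @export
degree_K <- function(ppi, gene) {
  if (!gene %in% igraph::V(ppi)$name)
    stop("gene '", gene, "' is not in the PPI network", call. = FALSE)
  as.integer(igraph::degree(ppi, gene))
}

#' Construct the depth-2 DEG-based local network of an EDG
#'
#' The local network of a source EDG contains the source, every
#' differentially expressed gene (DEG) within two hops of the source
#' (targets), and every non-source one-hop node adjacent to at least one
#' two-hop DEG (intermediates). A one-hop DEG that also bridges to a
#' two-hop DEG has both roles. Edges are those of the PPI network induced
#' on these nodes.
#'
#' @param ppi An igraph from [ppi_graph()].
#' @param source Source EDG gene id (must be a PPI node).
#' @param deg_set Character vector of DEG gene ids.
#' @param max_depth Neighborhood depth (the method is defined at 2).
#' @return An object of class `local_network`: list with `source`,
#'   `nodes` (data.frame `gene_id`, `role`), and `graph` (induced igraph).
#' @export
build_local_network <- function(ppi, source, deg_set, max_depth = 2) {
  if (!source %in% igraph::V(ppi)$name)
    stop("source '", source, "' is not in the PPI network", call. = FALSE)
  stopifnot(max_depth == 2)
  nb1 <- igraph::V(ppi)$name[igraph::neighbors(ppi, source)]
  d1 <- intersect(nb1, deg_set)
  hop2 <- setdiff(
    unique(unlist(lapply(nb1, function(u)
      igraph::V(ppi)$name[igraph::neighbors(ppi, u)]))),
    c(source, nb1))
  d2 <- intersect(hop2, deg_set)
  bridges <- nb1[vapply(nb1, function(u)
    any(igraph::V(ppi)$name[igraph::neighbors(ppi, u)] %in% d2), logical(1))]
  nodes <- unique(c(source, d1, d2, bridges))
  role <- vapply(nodes, function(v) {
    if (v == source) return("source")
    is_target <- v %in% d1 || v %in% d2
    is_inter <- v %in% bridges
    if (is_target && is_inter) "intermediate+target"
    else if (is_target) "target"
    else "intermediate"
  }, character(1))
  sub <- igraph::induced_subgraph(ppi, nodes)
  structure(list(source = source,
                 nodes = data.frame(gene_id = nodes, role = unname(role),
                                    stringsAsFactors = FALSE),
                 graph = sub),
            class = "local_network")
}

#' @export
print.local_network <- function(x, ...) {
  cat("Local network of", x$source, "-", nrow(x$nodes), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  print(table(x$nodes$role))
  invisible(x)
}

#' Number of nearest DEG neighbors, N(v)
#'
#' @param graph An igraph (local network or full PPI).
#' @param node Node id.
#' @param deg_set Character vector of DEG gene ids.
#' @return Integer count of direct neighbors of `node` that are DEGs.
#' @export
nearest_deg_count <- function(graph, node, deg_set) {
  if (!node %in% igraph::V(graph)$name) return(0L)
  nb <- igraph::V(graph)$name[igraph::neighbors(graph, node)]
  sum(nb %in% deg_set)
}

#' Next-nearest DEG influence, Q(v)
#'
#' Q(v) is the sum of N(u) over the direct neighbors u of v (u may or may
#' not itself be a DEG), with N(u) counted in the same graph.
#'
#' @inheritParams nearest_deg_count
#' @return Integer sum.
#' @export
q_value <- function(graph, node, deg_set) {
  if (!node %in% igraph::V(graph)$name) return(0L)
  nb <- igraph::V(graph)$name[igraph::neighbors(graph, node)]
  if (length(nb) == 0L) return(0L)
  sum(vapply(nb, function(u) nearest_deg_count(graph, u, deg_set), integer(1)))
}

#' Weighting coefficient alpha over the EDG set
#'
#' alpha = sum(N^2) / sum(Q) over the analyzed EDG set, distinguishing the
#' importance of nearest and next-nearest neighbors. When the denominator
#' is zero (no EDG reaches a next-nearest DEG), alpha is defined as 0, so
#' C_WL reduces to N.
#'
#' @param N Numeric vector of per-EDG nearest-DEG counts.
#' @param Q Numeric vector of per-EDG next-nearest sums (same length).
#' @return A single non-negative number.
#' @export
alpha_weight <- function(N, Q) {
  stopifnot(length(N) == length(Q))
  if (length(N) == 0L) stop("empty EDG set", call. = FALSE)
  denom <- sum(Q)
  if (denom == 0) return(0)
  sum(N^2) / denom
}

#' Weighted semi-local centrality C_WL(v) = N(v) + alpha * Q(v)
#'
#' @param N Nearest-DEG neighbor count(s).
#' @param Q Next-nearest sum(s).
#' @param alpha Weighting coefficient from [alpha_weight()].
#' @return Numeric, same length as `N`.
#' @export
c_wl <- function(N, Q, alpha) {
  stopifnot(all(N >= 0), all(Q >= 0), alpha >= 0)
  N + alpha * Q
}

#' EDG impact score EGIS(v) = (K(v) + 1) * (C_WL(v) + 1)
#'
#' @param K Degree centrality in the full PPI network.
#' @param C_WL Weighted semi-local centrality.
#' @return Numeric, same length as `K`.
#' @export
egis <- function(K, C_WL) {
  stopifnot(all(K >= 0), all(C_WL >= 0))
  (K + 1) * (C_WL + 1)
}

#' Filter a DEG table to the DEG gene set
#'
#' Applies the strict thresholds |log2FC| > `lfc_threshold` and
#' q < `q_threshold`. A table whose `log2FC`/`q_value` are all `NA` (a
#' precomputed gene list) passes through unfiltered.
#'
#' @param deg_table Data.frame from [read_deg_table()], or a character
#'   vector of gene ids.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param q_threshold Adjusted-p threshold (default 0.01).
#' @return Character vector of DEG gene ids.
#' @export
deg_gene_set <- function(deg_table, lfc_threshold = 1.0, q_threshold = 0.01) {
  if (is.character(deg_table)) return(unique(deg_table))
  stopifnot(is.data.frame(deg_table))
  if (nrow(deg_table) == 0L) return(character())
  if (all(is.na(deg_table$log2FC)))
    return(unique(deg_table$gene_id))
  keep <- abs(deg_table$log2FC) > lfc_threshold &
    deg_table$q_value < q_threshold
  unique(deg_table$gene_id[keep])
}

#' Rank EDGs by EGIS and select candidate eccDNA-driven drivers
#'
#' Implements the ranking core of the eccDriver algorithm. EDGs not
#' covered by the PPI network are removed; for each surviving EDG the
#' degree K is taken from the full PPI network, its depth-2 DEG-based
#' local network is built, N and Q are computed (within the local network
#' by default), one shared alpha is computed over the whole EDG set, and
#' EDGs are ranked by EGIS descending (ties by K descending, then gene id
#' ascending). The first `top_m` ranked EDGs are flagged as candidate
#' drivers.
#'
#' @param edg_genes Character vector of EDG gene ids, or an `edg_catalog`
#'   (its coding partition is used).
#' @param ppi An igraph from [ppi_graph()].
#' @param deg_table DEG table, precomputed gene list, or character vector
#'   (see [deg_gene_set()]).
#' @param top_m Number of top-ranked EDGs flagged as candidates
#'   (default 100).
#' @param lfc_threshold,q_threshold DEG filter thresholds (strict
#'   inequalities; defaults 1 and 0.01).
#' @param restrict_to_local If `TRUE` (default) N and Q are counted inside
#'   each EDG's local network; if `FALSE` they are counted in the full PPI
#'   network (sensitivity analysis).
#' @return A data.frame of class `driver_ranking` with columns `gene_id`,
#'   `K`, `N`, `Q`, `alpha_used`, `C_WL`, `EGIS`, `rank`, `candidate`,
#'   sorted by rank. The value of alpha is also attached as attribute
#'   `alpha`.
#' @export
rank_drivers <- function(edg_genes, ppi, deg_table, top_m = 100,
                         lfc_threshold = 1.0, q_threshold = 0.01,
                         restrict_to_local = TRUE) {
  if (inherits(edg_genes, "edg_catalog")) edg_genes <- edg_genes$coding
  edg_genes <- unique(edg_genes)
  deg_set <- deg_gene_set(deg_table, lfc_threshold, q_threshold)
  if (length(deg_set) == 0L)
    warning("no gene passes the DEG filters; all N and Q will be 0",
            call. = FALSE)
  keep <- edg_genes[edg_genes %in% igraph::V(ppi)$name]
  if (length(keep) == 0L)
    stop("no EDG is covered by the PPI network", call. = FALSE)
  K <- vapply(keep, function(g) degree_K(ppi, g), integer(1))
  NQ <- lapply(keep, function(g) {
    if (restrict_to_local) {
      ln <- build_local_network(ppi, g, deg_set)
      c(N = nearest_deg_count(ln$graph, g, deg_set),
        Q = q_value(ln$graph, g, deg_set))
    } else {
      c(N = nearest_deg_count(ppi, g, deg_set),
        Q = q_value(ppi, g, deg_set))
    }
  })
  N <- vapply(NQ, `[[`, numeric(1), "N")
  Q <- vapply(NQ, `[[`, numeric(1), "Q")
  alpha <- alpha_weight(N, Q)
  CWL <- c_wl(N, Q, alpha)
  score <- egis(K, CWL)
  out <- data.frame(gene_id = keep, K = unname(K), N = N, Q = Q,
                    alpha_used = alpha, C_WL = CWL, EGIS = score,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$EGIS, -out$K, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$candidate <- out$rank <= min(top_m, nrow(out))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("driver_ranking", class(out))
  out
}
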