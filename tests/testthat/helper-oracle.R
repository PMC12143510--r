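# Independent brute-force re-evaluation of the centrality definitions,
# written against a plain adjacency matrix so it shares no code with the
# package's igraph-based implementation.

# adj: symmetric 0/1 matrix with dimnames; deg_genes/edg_genes: character
oracle_centrality <- function(adj, deg_genes, edg_genes) {
  ids <- rownames(adj)
  stopifnot(identical(adj, t(adj)), all(diag(adj) == 0))
  per_edg <- lapply(edg_genes, function(v) {
    K <- sum(adj[v, ])
    nb1 <- ids[adj[v, ] == 1]
    d1 <- intersect(nb1, deg_genes)
    rest <- setdiff(ids, c(v, nb1))
    hop2 <- rest[vapply(rest, function(w) any(adj[w, nb1] == 1), logical(1))]
    d2 <- intersect(hop2, deg_genes)
    bridges <- nb1[vapply(nb1, function(u) any(adj[u, d2] == 1), logical(1))]
    nodes <- unique(c(v, d1, d2, bridges))
    sub <- adj[nodes, nodes, drop = FALSE]
    n_of <- function(x) sum(sub[x, ] == 1 & colnames(sub) %in% deg_genes)
    nb_local <- nodes[sub[v, ] == 1]
    list(K = K, N = n_of(v),
         Q = if (length(nb_local) == 0) 0 else
           sum(vapply(nb_local, n_of, numeric(1))))
  })
  N <- vapply(per_edg, `[[`, numeric(1), "N")
  Q <- vapply(per_edg, `[[`, numeric(1), "Q")
  K <- vapply(per_edg, `[[`, numeric(1), "K")
  alpha <- if (sum(Q) == 0) 0 else sum(N^2) / sum(Q)
  CWL <- N + alpha * Q
  data.frame(gene_id = edg_genes, K = K, N = N, Q = Q, alpha = alpha,
             C_WL = CWL, EGIS = (K + 1) * (CWL + 1),
             stringsAsFactors = FALSE)
}

# random simple graph as an adjacency matrix plus the package-side edge list
random_graph_fixture <- function(n, p_edge = 0.12, seed = 1) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  upper <- which(upper.tri(adj))
  adj[upper] <- rbinom(length(upper), 1L, p_edge)
  adj <- adj + t(adj)
  ij <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- data.frame(gene_a = ids[ij[, 1L]], gene_b = ids[ij[, 2L]],
                      confidence = 900, stringsAsFactors = FALSE)
  deg_genes <- ids[rbinom(n, 1L, 0.3) == 1L]
  n_edg <- max(1L, rbinom(1L, n, 0.2))
  edg_genes <- sort(sample(ids, n_edg))
  list(adj = adj, edges = edges, ids = ids,
       deg_genes = deg_genes, edg_genes = edg_genes)
}
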