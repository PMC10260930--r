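# Node centralities of the residue interaction network.
#
# Conventions (fixed; downstream steps — ranks, bins over observed ranges,
# Pareto dominance — are invariant to monotone rescalings):
#   * betweenness: unnormalized shortest-path pair counts
#   * closeness:   (nc-1)/sum(d) within the node's component, scaled by
#                  (nc-1)/(n-1) on disconnected graphs; stays in (0,1]
#   * authority:   HITS authority == eigenvector centrality on undirected
#                  graphs; power iteration, tolerance 1e-12, max-normalized
#   * pagerank:    damping 0.85, sums to 1

#' Compute the seven centrality measures of a contact graph
#'
#' Degree, betweenness, closeness, k-core number, Burt's constraint,
#' authority score and PageRank, one row per node. Deterministic.
#'
#' @param g a simplified igraph graph with named vertices
#' @return data.frame with columns residue, degree, betweenness, closeness,
#'   kcore, burts_constraint, authority, pagerank
#' @export
compute_centralities <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("cannot compute centralities of an empty graph")
  nm <- igraph::vertex_attr(g, "name") %||% as.character(seq_len(n))

  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)

  d <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    nc <- sum(reach) + 1L
    if (nc == 1L) return(0)
    base <- (nc - 1) / sum(di[reach])
    if (n > 1L) base * (nc - 1) / (n - 1) else base
  }, 0)

  kcore <- igraph::coreness(g)
  constraint <- igraph::constraint(g)

  structure_df <- data.frame(
    residue = nm,
    degree = as.integer(unname(deg)),
    betweenness = unname(btw),
    closeness = unname(clo),
    kcore = as.integer(unname(kcore)),
    burts_constraint = unname(constraint),
    authority = unname(authority_score(g)),
    pagerank = unname(igraph::page_rank(g, damping = 0.85)$vector),
    stringsAsFactors = FALSE
  )
  rownames(structure_df) <- NULL
  structure_df
}

#' HITS authority score by power iteration
#'
#' On an undirected graph the authority score coincides with eigenvector
#' centrality. Iterates x <- (A + I) x (the identity shift keeps the
#' dominant eigenpair while suppressing the sign oscillation on bipartite
#' graphs) with max-normalization until the sup-norm change is below `tol`.
#'
#' @param g an igraph graph
#' @param tol convergence tolerance (default 1e-12)
#' @param max_iter iteration cap
#' @return numeric vector, max value 1 on non-empty graphs
#' @export
authority_score <- function(g, tol = 1e-12, max_iter = 100000L) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(A %*% x) + x
    m <- max(x_new)
    if (m == 0) return(stats::setNames(rep(0, n), igraph::vertex_attr(g, "name")))
    x_new <- x_new / m
    if (max(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  stats::setNames(x, igraph::vertex_attr(g, "name"))
}

#' Spearman rank-correlation matrix of the centrality measures
#'
#' @param tab a centrality table from [compute_centralities()]
#' @return symmetric 7x7 matrix; unit diagonal; a constant measure yields
#'   `NA` against the others (undefined, not zero)
#' @export
spearman_matrix <- function(tab) {
  measures <- c("degree", "betweenness", "closeness", "kcore",
                "burts_constraint", "authority", "pagerank")
  stopifnot(all(measures %in% names(tab)))
  if (nrow(tab) < 3L) stop("need at least 3 rows for a rank correlation")
  m <- suppressWarnings(stats::cor(as.matrix(tab[, measures]),
                                   method = "spearman",
                                   use = "pairwise.complete.obs"))
  diag(m) <- 1
  m
}
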