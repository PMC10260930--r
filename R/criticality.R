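# Criticality classification of residues.
#
# The degree / log10-betweenness plane is divided into 4 uniform bins per
# axis; residues in the extreme bin combinations are labelled HDHB (top
# degree x top betweenness), LDHB (bottom x top) and LDLB (bottom x
# bottom). Residues with zero betweenness cannot be placed on the log axis
# and stay UNCLASSIFIED. The "supercritical" set is the Pareto front
# maximizing degree, betweenness and closeness simultaneously.

#' Uniform bin edges over an axis
#'
#' Half-open `(lo, hi]` bins spanning the observed range; the lowest edge
#' is nudged down by 0.1% of the range so the minimum value falls inside
#' the first bin.
#'
#' @param x numeric values
#' @param n_bins number of bins (default 4)
#' @return numeric vector of `n_bins + 1` ascending edges
#' @export
bin_edges <- function(x, n_bins = 4L) {
  if (length(unique(x)) < 2L) {
    stop("cannot bin an axis with fewer than 2 distinct values")
  }
  lo <- min(x); hi <- max(x)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  edges[1L] <- lo - 0.001 * (hi - lo)
  edges
}

# bin index under the (lo, hi] convention
bin_index <- function(x, edges) {
  findInterval(x, edges, left.open = TRUE, rightmost.closed = FALSE)
}

#' Classify residues into HDHB / LDHB / LDLB criticality groups
#'
#' Residues with positive betweenness are placed on the degree vs
#' log10(betweenness) plane, each axis divided into `n_bins` uniform
#' half-open bins over its observed range. Labels: HDHB = top degree bin
#' and top log-betweenness bin; LDHB = bottom degree bin, top
#' log-betweenness bin; LDLB = bottom bin on both axes; every other
#' combination — and every zero-betweenness residue — is UNCLASSIFIED.
#'
#' @param tab centrality table from [compute_centralities()]
#' @param n_bins bins per axis (4 reproduces the published grouping; other
#'   values are accepted but untested against it)
#' @return list with `labels` (data.frame: residue, degree,
#'   log10_betweenness, degree_bin, logbet_bin, label) and `grid`
#'   (list: degree_edges, logbet_edges)
#' @export
bin_criticality <- function(tab, n_bins = 4L) {
  stopifnot(all(c("residue", "degree", "betweenness") %in% names(tab)))
  inc <- tab$betweenness > 0
  if (sum(inc) < 2L) stop("fewer than 2 residues with positive betweenness")

  deg <- tab$degree[inc]
  logbet <- log10(tab$betweenness[inc])
  deg_edges <- bin_edges(deg, n_bins)
  lb_edges <- bin_edges(logbet, n_bins)

  deg_bin <- rep(NA_integer_, nrow(tab))
  lb_bin <- rep(NA_integer_, nrow(tab))
  deg_bin[inc] <- bin_index(deg, deg_edges)
  lb_bin[inc] <- bin_index(logbet, lb_edges)

  label <- rep("UNCLASSIFIED", nrow(tab))
  label[inc & deg_bin == n_bins & lb_bin == n_bins] <- "HDHB"
  label[inc & deg_bin == 1L & lb_bin == n_bins] <- "LDHB"
  label[inc & deg_bin == 1L & lb_bin == 1L] <- "LDLB"

  list(
    labels = data.frame(
      residue = tab$residue,
      degree = tab$degree,
      log10_betweenness = ifelse(inc, log10(pmax(tab$betweenness, .Machine$double.xmin)), NA_real_),
      degree_bin = deg_bin, logbet_bin = lb_bin, label = label,
      stringsAsFactors = FALSE
    ),
    grid = list(degree_edges = deg_edges, logbet_edges = lb_edges)
  )
}

#' Pareto-front "supercritical" residues
#'
#' Returns the residues not strictly dominated in (degree, betweenness,
#' closeness) under maximization: x dominates y iff x >= y on all three
#' objectives and x > y on at least one. All non-dominated ties are kept.
#'
#' Implementation: points are scanned in lexicographically decreasing
#' order, so any dominator of a point precedes it and (by transitivity) a
#' front member dominates it; each point is therefore checked against the
#' current front only.
#'
#' @param tab centrality table
#' @param objectives column names to maximize
#' @return character vector of residue keys on the front, in table order
#' @export
pareto_supercritical <- function(tab,
                                 objectives = c("degree", "betweenness", "closeness")) {
  stopifnot(all(objectives %in% names(tab)), nrow(tab) >= 1L)
  m <- as.matrix(tab[, objectives, drop = FALSE])
  ord <- do.call(order, c(lapply(seq_along(objectives), function(j) -m[, j])))
  front <- integer(0)
  for (i in ord) {
    dominated <- FALSE
    for (f in front) {
      if (all(m[f, ] >= m[i, ]) && any(m[f, ] > m[i, ])) { dominated <- TRUE; break }
    }
    if (!dominated) front <- c(front, i)
  }
  tab$residue[sort(front)]
}
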