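# Residue interaction network construction.
#
# Two residues are connected if any atom pair (a in i, b in j) satisfies
# dist(a,b) <= vdw(a) + vdw(b) + 2*probe_radius: the first-order criterion
# for two van der Waals surfaces both touched by a probe sphere rolled
# between them. The graph is simple, undirected and unweighted; contact
# categories (side-chain/main-chain) are edge metadata only.

#' Contact rule for RIN construction
#'
#' @param probe_radius probe sphere radius in Angstrom (default 0.25)
#' @param vdw_table element -> van der Waals radius, Angstrom
#' @param min_seq_separation minimum |i - j| (ordinal positions within a
#'   chain) for an edge; the default 1 excludes only self-contacts, so
#'   sequence-adjacent residues may be connected
#' @param heavy_atoms_only if `TRUE` (default) hydrogens are ignored; the
#'   inflated heavy-atom radii compensate for the absent protons
#' @return a list of class `fv_contact_rule`
#' @export
contact_rule <- function(probe_radius = 0.25, vdw_table = default_vdw_radii(),
                         min_seq_separation = 1L, heavy_atoms_only = TRUE) {
  stopifnot(probe_radius >= 0, all(vdw_table > 0), min_seq_separation >= 0)
  structure(
    list(probe_radius = probe_radius, vdw_table = vdw_table,
         min_seq_separation = as.integer(min_seq_separation),
         heavy_atoms_only = heavy_atoms_only),
    class = "fv_contact_rule"
  )
}

#' Build the residue interaction network of a structure
#'
#' Nodes are all residues of `structure` (keyed `"chain:seqnum:icode"`);
#' an edge joins residues i and j when some atom pair is within
#' `vdw_i + vdw_j + 2 * probe_radius`. Each edge carries a `kind`
#' attribute — `SS`, `SM` or `MM` — from the backbone membership of the
#' closest qualifying atom pair (backbone = N, CA, C, O).
#'
#' @param structure an `fv_structure`
#' @param rule an `fv_contact_rule`
#' @param chains optional chain filter (character vector)
#' @return an [igraph][igraph::igraph-package] graph, already simplified,
#'   with vertex attribute `name` = residue key
#' @export
build_rin <- function(structure, rule = contact_rule(), chains = NULL) {
  stopifnot(inherits(structure, "fv_structure"), inherits(rule, "fv_contact_rule"))
  atoms <- structure$atoms
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("structure has no atoms (after chain filtering)")

  key_all <- residue_key(atoms$chain, atoms$seqnum, atoms$icode)
  nodes <- unique(key_all)

  if (rule$heavy_atoms_only) {
    use <- atoms$element != "H"
  } else {
    use <- rep(TRUE, nrow(atoms))
  }
  radius <- unname(rule$vdw_table[atoms$element])
  unknown <- use & is.na(radius)
  if (any(unknown)) {
    warning(sprintf("%d atom(s) with element outside the vdW table ignored (%s)",
                    sum(unknown), paste(unique(atoms$element[unknown]), collapse = ", ")))
    use <- use & !is.na(radius)
  }
  atoms <- atoms[use, , drop = FALSE]
  radius <- radius[use]
  key <- key_all[use]

  bare <- setdiff(nodes, unique(key))
  if (length(bare) > 0L) {
    warning(sprintf("%d residue(s) with no usable atoms under the rule kept as isolated nodes: %s",
                    length(bare), paste(bare, collapse = ", ")))
  }

  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(atoms) == 0L) return(g)

  # ordinal position within chain, for the sequence-separation rule
  rt <- data.frame(key = nodes, split_residue_key(nodes))
  pos_in_chain <- stats::ave(seq_len(nrow(rt)), rt$chain, FUN = seq_along)
  names(pos_in_chain) <- rt$key
  chain_of <- rt$chain
  names(chain_of) <- rt$key

  max_cut <- 2 * max(radius) + 2 * rule$probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  idx_by_res <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  res_names <- names(idx_by_res)
  centroid <- t(vapply(idx_by_res, function(ii) colMeans(xyz[ii, , drop = FALSE]),
                       numeric(3L)))
  reach <- vapply(seq_along(idx_by_res), function(r) {
    ii <- idx_by_res[[r]]
    sqrt(max(rowSums((xyz[ii, , drop = FALSE] -
                      matrix(centroid[r, ], length(ii), 3L, byrow = TRUE))^2)))
  }, 0)

  nres <- length(idx_by_res)
  efrom <- character(0); eto <- character(0); ekind <- character(0)
  bb <- atoms$is_backbone
  for (r1 in seq_len(nres - 1L)) {
    ii <- idx_by_res[[r1]]
    d_cent <- sqrt(rowSums((centroid[(r1 + 1L):nres, , drop = FALSE] -
                            matrix(centroid[r1, ], nres - r1, 3L, byrow = TRUE))^2))
    cand <- which(d_cent <= reach[r1] + reach[(r1 + 1L):nres] + max_cut) + r1
    for (r2 in cand) {
      k1 <- res_names[r1]; k2 <- res_names[r2]
      if (chain_of[k1] == chain_of[k2] &&
          abs(pos_in_chain[k1] - pos_in_chain[k2]) < rule$min_seq_separation) next
      jj <- idx_by_res[[r2]]
      d2 <- outer(rowSums(xyz[ii, , drop = FALSE]^2),
                  rowSums(xyz[jj, , drop = FALSE]^2), "+") -
        2 * tcrossprod(xyz[ii, , drop = FALSE], xyz[jj, , drop = FALSE])
      d2[d2 < 0] <- 0
      thresh <- outer(radius[ii], radius[jj], "+") + 2 * rule$probe_radius
      hit <- sqrt(d2) - thresh
      if (any(hit <= 0)) {
        best <- which(hit == min(hit), arr.ind = TRUE)[1L, ]
        b1 <- bb[ii[best[1L]]]; b2 <- bb[jj[best[2L]]]
        efrom <- c(efrom, k1); eto <- c(eto, k2)
        ekind <- c(ekind, if (b1 && b2) "MM" else if (!b1 && !b2) "SS" else "SM")
      }
    }
  }

  if (length(efrom) > 0L) {
    g <- igraph::add_edges(g, rbind(match(efrom, nodes), match(eto, nodes)),
                           kind = ekind)
  }
  simplify_graph(g)
}

#' Remove duplicate edges and self-loops from a contact graph
#'
#' Idempotent; the node set is preserved. Edge attributes of collapsed
#' duplicates keep the first value.
#'
#' @param g an igraph graph
#' @return the simplified graph
#' @export
simplify_graph <- function(g) {
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' Edge table of a contact graph
#'
#' @param g a RIN from [build_rin()]
#' @return data.frame: chain_i, seq_i, icode_i, chain_j, seq_j, icode_j, kind
#' @export
rin_edge_table <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) {
    return(data.frame(chain_i = character(0), seq_i = integer(0),
                      icode_i = character(0), chain_j = character(0),
                      seq_j = integer(0), icode_j = character(0),
                      kind = character(0)))
  }
  a <- split_residue_key(el[, 1L]); b <- split_residue_key(el[, 2L])
  kind <- igraph::edge_attr(g, "kind") %||% rep(NA_character_, nrow(el))
  data.frame(chain_i = a$chain, seq_i = a$seqnum, icode_i = a$icode,
             chain_j = b$chain, seq_j = b$seqnum, icode_j = b$icode,
             kind = kind, stringsAsFactors = FALSE)
}

#' Export a contact graph in SIF format for external viewers
#'
#' @param g a RIN
#' @param path output file
#' @export
write_sif <- function(g, path) {
  el <- igraph::as_edgelist(g)
  kind <- igraph::edge_attr(g, "kind") %||% rep("contact", nrow(el))
  writeLines(sprintf("%s %s %s", el[, 1L], tolower(kind), el[, 2L]), path)
}
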