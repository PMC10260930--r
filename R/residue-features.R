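# Per-residue structural features and assembly of the 14-feature matrix.
#
# The feature block is: 6 structural (Kyte-Doolittle hydrophobicity, SASA,
# SESA, relative SESA, phi, psi) + 7 network centralities + 1 evolutionary
# conservation score (imported; low values = high conservation).

.kd_scale <- c(
  ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
  GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
  LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
  SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2
)

#' Fixed, ordered registry of the 14 feature names
#' @return character vector of length 14
#' @export
feature_registry <- function() {
  c("kd_hydrophobicity", "sasa", "sesa", "relative_sesa", "phi", "psi",
    "degree", "betweenness", "closeness", "kcore", "burts_constraint",
    "authority", "pagerank", "conservation")
}

#' Kyte-Doolittle hydropathy of a standard amino acid
#'
#' @param resname 3-letter code(s)
#' @return numeric vector of scale values
#' @export
kd_hydrophobicity <- function(resname) {
  resname <- toupper(resname)
  bad <- !(resname %in% names(.kd_scale))
  if (any(bad)) {
    stop("unknown residue name(s): ", paste(unique(resname[bad]), collapse = ", "))
  }
  unname(.kd_scale[resname])
}

# signed dihedral (IUPAC convention), degrees; NA on degenerate geometry
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-9 || sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / nb2
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedral angles
#'
#' Computed per chain, in file order; a peptide bond longer than
#' `break_cutoff` between consecutive residues is treated as a chain break
#' (both flanks become termini). Terminal residues have undefined phi
#' (first) / psi (last), stored as `NA`; so is any residue missing a
#' required backbone atom or with degenerate (collinear) geometry.
#'
#' @param s an `fv_structure`
#' @param break_cutoff C(i)-N(i+1) distance above which the chain is
#'   considered broken, Angstrom (default 2.5)
#' @return data.frame: residue, phi, psi (degrees, in (-180, 180])
#' @export
backbone_dihedrals <- function(s, break_cutoff = 2.5) {
  stopifnot(inherits(s, "fv_structure"))
  rt <- residue_table(s)
  a <- s$atoms
  key <- residue_key(a$chain, a$seqnum, a$icode)

  bb_coord <- function(res, name) {
    i <- which(key == res & a$atom == name)
    if (length(i) == 0L) return(NULL)
    c(a$x[i[1L]], a$y[i[1L]], a$z[i[1L]])
  }

  phi <- rep(NA_real_, nrow(rt)); psi <- rep(NA_real_, nrow(rt))
  for (ch in unique(rt$chain)) {
    idx <- which(rt$chain == ch)
    N <- lapply(rt$residue[idx], bb_coord, "N")
    CA <- lapply(rt$residue[idx], bb_coord, "CA")
    C <- lapply(rt$residue[idx], bb_coord, "C")
    linked <- function(i) {  # peptide bond i -> i+1 intact
      !is.null(C[[i]]) && !is.null(N[[i + 1L]]) &&
        sqrt(sum((C[[i]] - N[[i + 1L]])^2)) <= break_cutoff
    }
    for (j in seq_along(idx)) {
      if (j > 1L && linked(j - 1L) &&
          !is.null(N[[j]]) && !is.null(CA[[j]]) && !is.null(C[[j]])) {
        phi[idx[j]] <- dihedral_angle(C[[j - 1L]], N[[j]], CA[[j]], C[[j]])
      }
      if (j < length(idx) && linked(j) &&
          !is.null(N[[j]]) && !is.null(CA[[j]]) && !is.null(C[[j]])) {
        psi[idx[j]] <- dihedral_angle(N[[j]], CA[[j]], C[[j]], N[[j + 1L]])
      }
    }
  }
  data.frame(residue = rt$residue, phi = phi, psi = psi, stringsAsFactors = FALSE)
}

# deterministic golden-spiral point set on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` deterministic golden-spiral points on each atom's
#' expanded sphere (vdW radius + probe) and counts points not buried in
#' any neighbouring expanded sphere; per-residue areas are sums over the
#' residue's atoms. An isolated atom yields its full expanded-sphere area
#' 4*pi*(r+probe)^2.
#'
#' @param s an `fv_structure`
#' @param probe probe radius, Angstrom (default 1.4, water)
#' @param n_points sphere sample points per atom (default 960)
#' @param vdw_table element -> radius table
#' @return data.frame: residue, sasa (Angstrom^2)
#' @export
sasa <- function(s, probe = 1.4, n_points = 960L, vdw_table = default_vdw_radii()) {
  stopifnot(inherits(s, "fv_structure"), probe >= 0, n_points >= 12L)
  a <- s$atoms
  radius <- unname(vdw_table[a$element])
  if (anyNA(radius)) {
    stop("atoms with element outside the vdW table: ",
         paste(unique(a$element[is.na(radius)]), collapse = ", "))
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- radius + probe
  pts <- sphere_points(n_points)
  n_atoms <- nrow(a)
  area <- numeric(n_atoms)
  max_R <- max(R)

  for (i in seq_len(n_atoms)) {
    d2 <- rowSums((xyz - matrix(xyz[i, ], n_atoms, 3L, byrow = TRUE))^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n_atoms) != i)
    if (length(nb) == 0L) { area[i] <- 4 * pi * R[i]^2; next }
    p <- pts * R[i] + matrix(xyz[i, ], n_points, 3L, byrow = TRUE)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums((p[free, , drop = FALSE] -
                     matrix(xyz[j, ], sum(free), 3L, byrow = TRUE))^2)
      free[free] <- dj >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }

  key <- residue_key(a$chain, a$seqnum, a$icode)
  per_res <- tapply(area, factor(key, levels = unique(key)), sum)
  data.frame(residue = names(per_res), sasa = as.numeric(per_res),
             stringsAsFactors = FALSE)
}

#' Gly-X-Gly reference surface areas
#'
#' Per-residue-type reference areas (Angstrom^2) of residue X in an
#' extended Gly-X-Gly tripeptide, used as the denominator of the relative
#' accessibility. Bundled as an editable CSV (Tien-style theoretical
#' values).
#'
#' @param path optional path to an alternative reference CSV
#'   (columns resname, area)
#' @return named numeric vector, 3-letter code -> area
#' @export
gxg_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gxg_reference_areas.csv",
                                package = "fvrin", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(ref$area, toupper(ref$resname))
}

#' Relative accessibility of a residue
#'
#' @param area observed surface area, Angstrom^2
#' @param resname 3-letter code(s)
#' @param reference named reference table (default [gxg_reference()])
#' @return `area / reference[resname]`
#' @export
relative_accessibility <- function(area, resname, reference = gxg_reference()) {
  resname <- toupper(resname)
  ref <- unname(reference[resname])
  if (anyNA(ref) || any(ref == 0)) {
    stop("missing or zero reference area for: ",
         paste(unique(resname[is.na(ref) | ref == 0]), collapse = ", "))
  }
  area / ref
}

#' Compute the structural feature block of a structure
#'
#' Produces the 6 structural columns of the feature matrix. The
#' solvent-excluded area (SESA) is an import-only column by default (pass
#' a data.frame `sesa` with columns residue, sesa); with
#' `approximate_sesa = TRUE` a labelled fallback — Shrake-Rupley sampling
#' at probe radius 0, i.e. the bare van der Waals surface — is used
#' instead and marked as such in the provenance attribute.
#'
#' @param s an `fv_structure`
#' @param sesa optional imported SESA table (residue, sesa)
#' @param approximate_sesa use the probe-0 fallback when no import is given
#' @param probe,n_points passed to [sasa()]
#' @param reference Gly-X-Gly reference areas
#' @return data.frame: residue, kd_hydrophobicity, sasa, sesa,
#'   relative_sesa, phi, psi; attribute `provenance` maps each feature to
#'   `"computed"`, `"imported"` or `"computed_approximate"`
#' @export
compute_structural_features <- function(s, sesa = NULL, approximate_sesa = is.null(sesa),
                                        probe = 1.4, n_points = 960L,
                                        reference = gxg_reference()) {
  rt <- residue_table(s)
  acc <- sasa(s, probe = probe, n_points = n_points)
  dih <- backbone_dihedrals(s)

  prov <- c(kd_hydrophobicity = "computed", sasa = "computed",
            sesa = "imported", relative_sesa = "imported",
            phi = "computed", psi = "computed")
  if (!is.null(sesa)) {
    stopifnot(all(c("residue", "sesa") %in% names(sesa)))
    sesa_val <- sesa$sesa[match(rt$residue, sesa$residue)]
  } else if (approximate_sesa) {
    sesa_val <- sasa(s, probe = 0, n_points = n_points)$sasa
    prov[c("sesa", "relative_sesa")] <- "computed_approximate"
  } else {
    sesa_val <- rep(NA_real_, nrow(rt))
  }

  out <- data.frame(
    residue = rt$residue,
    kd_hydrophobicity = kd_hydrophobicity(rt$resname),
    sasa = acc$sasa[match(rt$residue, acc$residue)],
    sesa = sesa_val,
    relative_sesa = ifelse(is.na(sesa_val), NA_real_,
                           relative_accessibility(sesa_val, rt$resname, reference)),
    phi = dih$phi[match(rt$residue, dih$residue)],
    psi = dih$psi[match(rt$residue, dih$residue)],
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- prov
  out
}

#' Assemble the 14-feature matrix with the binary deficiency label
#'
#' Joins the structural block, the centrality table and the imported
#' conservation column on the residue key, attaches the 0/1 label, and
#' applies the discard rule: rows with any missing feature value, or with
#' zero betweenness centrality, are dropped and logged with their reason.
#'
#' @param centralities table from [compute_centralities()]
#' @param structural table from [compute_structural_features()] (or an
#'   equivalent imported data.frame)
#' @param conservation data.frame (residue, conservation); low values
#'   indicate high conservation
#' @param labels data.frame (residue, label) with label in 0/1, or a
#'   character vector of deficiency-residue keys; unlisted residues get 0
#' @return data.frame: residue, the 14 registry features, label;
#'   attributes `drop_log` (data.frame residue, reason) and `provenance`
#' @export
assemble_feature_matrix <- function(centralities, structural, conservation, labels) {
  stopifnot(all(c("residue", "conservation") %in% names(conservation)))
  fm <- merge(structural, centralities, by = "residue", sort = FALSE)
  fm <- merge(fm, conservation[, c("residue", "conservation")],
              by = "residue", sort = FALSE)
  fm <- fm[order_residue_keys(fm$residue), , drop = FALSE]

  if (is.character(labels)) {
    labels <- data.frame(residue = labels, label = 1L, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("residue", "label") %in% names(labels)))
  orphan <- setdiff(labels$residue[labels$label == 1L], fm$residue)
  if (length(orphan) > 0L) {
    warning("label(s) for residue(s) absent from the structure ignored: ",
            paste(orphan, collapse = ", "))
  }
  fm$label <- ifelse(fm$residue %in% labels$residue[labels$label == 1L], 1L, 0L)

  feats <- feature_registry()
  missing_feats <- setdiff(feats, names(fm))
  if (length(missing_feats) > 0L) {
    stop("feature column(s) absent from inputs: ", paste(missing_feats, collapse = ", "))
  }
  fm <- fm[, c("residue", feats, "label")]

  reason <- rep(NA_character_, nrow(fm))
  zero_b <- fm$betweenness == 0
  reason[zero_b] <- "zero betweenness"
  for (f in feats) {
    miss <- is.na(fm[[f]]) & is.na(reason)
    reason[miss] <- paste("missing", f)
  }
  drop <- !is.na(reason)
  drop_log <- data.frame(residue = fm$residue[drop], reason = reason[drop],
                         stringsAsFactors = FALSE)
  out <- fm[!drop, , drop = FALSE]
  rownames(out) <- NULL

  prov <- attr(structural, "provenance") %||%
    stats::setNames(rep("imported", 6L), feats[1:6])
  prov <- c(prov, stats::setNames(rep("computed", 7L), feats[7:13]),
            conservation = "imported")
  attr(out, "drop_log") <- drop_log
  attr(out, "provenance") <- prov
  out
}
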