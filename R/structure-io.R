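# PDB structure input/output.
#
# The internal coordinate model is a plain data.frame of atoms grouped into
# residues by the (chain, seqnum, icode) key; parsing is delegated to
# bio3d::read.pdb, after which HETATM groups are excluded, one atom is kept
# per alternate-location group, and non-standard residues are mapped onto
# their parent amino acid.

# 3-letter codes of the 20 standard amino acids
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Map of non-standard residue names onto their parent amino acid
#'
#' Small editable table consulted during parsing; residues not listed here
#' and not standard are dropped (with the HETATM groups).
#'
#' @return named character vector, non-standard code -> standard code
#' @export
nonstandard_residue_map <- function() {
  c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO", SEP = "SER",
    TPO = "THR", PTR = "TYR", MLY = "LYS", CSO = "CYS")
}

#' Parse a PDB-format structure
#'
#' Reads ATOM records into the package's coordinate model. Only amino-acid
#' residues are retained (HETATM ligands and waters are excluded); one atom
#' is kept per alternate-location group; non-standard residues are renamed
#' to their parent amino acid via [nonstandard_residue_map()].
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines
#' @param model_index which MODEL to read (1-based; default first)
#' @param altloc_policy `"occupancy"` keeps the highest-occupancy alternate
#'   (ties broken by file order), `"first"` keeps the first encountered
#' @param residue_map editable non-standard -> standard residue table
#' @return an object of class `fv_structure`: a list with element `atoms`,
#'   a data.frame with one row per atom (chain, seqnum, icode, resname,
#'   atom, element, x, y, z, occupancy, altloc, is_backbone)
#' @export
parse_structure <- function(pdb, model_index = 1L,
                            altloc_policy = c("occupancy", "first"),
                            residue_map = nonstandard_residue_map()) {
  altloc_policy <- match.arg(altloc_policy)

  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    path <- pdb
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
  }

  atom_lines <- grep("^ATOM  ", lines)
  if (length(atom_lines) == 0L) {
    stop("no ATOM records found in PDB input")
  }
  # validate the fixed-column coordinate fields before handing off
  for (i in atom_lines) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop(sprintf("malformed coordinates on line %d: '%s'", i, lines[i]))
    }
  }

  multi <- model_index > 1L
  pdbobj <- suppressWarnings(bio3d::read.pdb(path, multi = multi,
                                             rm.alt = FALSE, verbose = FALSE))
  at <- pdbobj$atom

  if (multi) {
    nmod <- nrow(pdbobj$xyz)
    if (model_index > nmod) {
      stop(sprintf("model %d requested but file has %d model(s)", model_index, nmod))
    }
    xyz <- matrix(pdbobj$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }

  at <- at[at$type == "ATOM", , drop = FALSE]
  resname <- toupper(at$resid)
  mapped <- !is.na(match(resname, names(residue_map)))
  resname[mapped] <- residue_map[resname[mapped]]
  keep <- resname %in% .standard_aa
  at <- at[keep, , drop = FALSE]
  resname <- resname[keep]
  if (nrow(at) == 0L) {
    stop("model contains no amino-acid ATOM records")
  }

  element <- toupper(trimws(at$elesy))
  noel <- is.na(element) | element == ""
  element[noel] <- toupper(substr(trimws(at$elety[noel]), 1L, 1L))
  occ <- at$o
  occ[is.na(occ)] <- 1.0
  alt <- trimws(at$alt)
  alt[is.na(alt)] <- ""
  icode <- trimws(at$insert)
  icode[is.na(icode)] <- ""
  chain <- at$chain
  chain[is.na(chain)] <- ""

  atoms <- data.frame(
    chain = chain, seqnum = as.integer(at$resno), icode = icode,
    resname = resname, atom = trimws(at$elety), element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = occ, altloc = alt,
    stringsAsFactors = FALSE
  )
  atoms$is_backbone <- atoms$atom %in% c("N", "CA", "C", "O")

  # one atom per altloc group (residue + atom name)
  if (any(atoms$altloc != "")) {
    grp <- paste(atoms$chain, atoms$seqnum, atoms$icode, atoms$atom, sep = "\r")
    ord <- if (altloc_policy == "occupancy") {
      order(grp, -atoms$occupancy)  # stable: ties keep file order
    } else {
      seq_len(nrow(atoms))
    }
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$seqnum, atoms$icode,
                                     atoms$atom, sep = "\r")), , drop = FALSE]
    atoms <- atoms[order_atoms_file(atoms), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  structure(list(atoms = atoms), class = "fv_structure")
}

# restore residue-then-atom file order after altloc resolution
order_atoms_file <- function(atoms) {
  key <- residue_key(atoms$chain, atoms$seqnum, atoms$icode)
  order(match(key, unique(key)))
}

#' Residue table of a structure
#'
#' @param s an `fv_structure`
#' @return data.frame with one row per residue: residue (key), chain,
#'   seqnum, icode, resname, n_atoms, in structure (file) order
#' @export
residue_table <- function(s) {
  stopifnot(inherits(s, "fv_structure"))
  a <- s$atoms
  key <- residue_key(a$chain, a$seqnum, a$icode)
  first <- !duplicated(key)
  data.frame(
    residue = key[first], chain = a$chain[first], seqnum = a$seqnum[first],
    icode = a$icode[first], resname = a$resname[first],
    n_atoms = as.integer(table(key)[key[first]]),
    stringsAsFactors = FALSE
  )
}

#' @export
print.fv_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("fv_structure: %d residues, %d atoms, %d chain(s)\n",
              nrow(rt), nrow(x$atoms), length(unique(rt$chain))))
  invisible(x)
}

#' Write a structure as minimal PDB ATOM records
#'
#' Emits fixed-column ATOM lines (plus TER/END) sufficient to round-trip
#' through [parse_structure()]; used for fixtures.
#'
#' @param s an `fv_structure`
#' @param path output file; if `NULL`, the lines are returned invisibly
#' @return character vector of PDB lines, invisibly
#' @export
write_pdb <- function(s, path = NULL) {
  stopifnot(inherits(s, "fv_structure"))
  a <- s$atoms
  name4 <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom), a$atom)
  lines <- sprintf(
    "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name4, ifelse(a$altloc == "", " ", a$altloc),
    a$resname, ifelse(a$chain == "", " ", a$chain), a$seqnum,
    ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, a$occupancy, 0, a$element
  )
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
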