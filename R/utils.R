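#' Default van der Waals radii (heavy atoms + hydrogen), in Angstrom
#'
#' Editable element -> radius table used by the contact rule and the
#' surface-area sampler.
#'
#' @return Named numeric vector of radii.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80, SE = 1.90)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers never
#' perturb the global random stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a residue key string
#'
#' Residues are identified throughout the package by the triple
#' (chain, author sequence number, insertion code), serialized as
#' `"chain:seqnum:icode"`. The total ordering is (chain, seqnum, icode).
#'
#' @param chain chain identifier
#' @param seqnum integer author numbering
#' @param icode insertion code, `""` if none
#' @return character vector of keys
#' @export
residue_key <- function(chain, seqnum, icode = "") {
  icode[is.na(icode)] <- ""
  paste(chain, seqnum, icode, sep = ":")
}

#' Split residue keys back into their components
#'
#' @param key character vector of `"chain:seqnum:icode"` keys
#' @return data.frame with columns chain, seqnum, icode
#' @export
split_residue_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chain  = vapply(parts, `[`, "", 1L),
    seqnum = as.integer(vapply(parts, `[`, "", 2L)),
    icode  = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
    stringsAsFactors = FALSE
  )
}

# order() permutation for residue keys under the (chain, seqnum, icode) ordering
order_residue_keys <- function(key) {
  k <- split_residue_key(key)
  order(k$chain, k$seqnum, k$icode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
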