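# SMILES -> molecule records.
#
# A molgat_mol couples the raw-SMILES token scan (the node-order authority)
# with RDKit's perception of atoms, bonds and - when requested - a seeded 3D
# conformer. The token order / RDKit order identity is checked on every
# parse, not assumed.

.hybridization_levels <- c(UNSPECIFIED = 0L, S = 1L, SP = 2L, SP2 = 3L,
                           SP3 = 4L, SP3D = 5L, SP3D2 = 6L)

.hybridization_code <- function(label) {
  code <- unname(.hybridization_levels[label])
  code[is.na(code)] <- 0L
  code
}

.mol_from_record <- function(smiles, tokens, rec) {
  el <- unlist(rec$atoms$element)
  if (length(el) != nrow(tokens) || !all(el == tokens$element)) {
    rlang::abort(
      paste0("backend atom order disagrees with SMILES token order for ",
             smiles),
      class = "molgat_parse_error")
  }
  n <- length(el)
  atoms <- tibble::tibble(
    position = seq_len(n),
    element = el,
    atomic_number = as.integer(unlist(rec$atoms$atomic_number)),
    aromatic = as.logical(unlist(rec$atoms$aromatic)),
    degree = as.integer(unlist(rec$atoms$degree)),
    n_h = as.integer(unlist(rec$atoms$n_h)),
    valence = as.integer(unlist(rec$atoms$valence)),
    formal_charge = as.integer(unlist(rec$atoms$formal_charge)),
    radical_electrons = as.integer(unlist(rec$atoms$radical_electrons)),
    has_implicit_h = as.logical(unlist(rec$atoms$has_implicit_h)),
    hybridization = .hybridization_code(unlist(rec$atoms$hybridization)))
  bonds <- if (length(rec$bonds) == 0L) {
    tibble::tibble(i = integer(), j = integer())
  } else {
    bm <- do.call(rbind, lapply(rec$bonds, unlist))
    tibble::tibble(i = as.integer(bm[, 1L]) + 1L,
                   j = as.integer(bm[, 2L]) + 1L)
  }
  geometry <- NULL
  geometry_error <- NULL
  if (!is.null(rec$geometry)) {
    g <- rec$geometry
    if (!is.null(g$error)) {
      geometry_error <- g$error
    } else {
      geometry <- list(
        coords = do.call(rbind, lapply(g$coords, unlist)),
        charges = unlist(g$charges),
        n_heavy = g$n_heavy,
        volume = g$volume,
        force_field = g$force_field,
        charge_model = g$charge_model)
    }
  }
  structure(
    list(smiles = smiles, atoms = atoms, bonds = bonds,
         descriptors = rec$descriptors,
         geometry = geometry, geometry_error = geometry_error),
    class = "molgat_mol")
}

# Vectorized SMILES parsing through one backend call. Returns
# list(mols, failed): `mols` has NULL at failed positions, `failed` the
# 1-based indices the token scanner or RDKit rejected. Geometry failures do
# NOT appear in `failed`; they are flagged on the molecule so the caller can
# apply drop_failed_geometry() semantics.
mols_from_smiles <- function(smiles, gen3d = FALSE, seed = 0L) {
  tokens <- lapply(smiles, function(s) {
    tryCatch(smiles_atom_tokens(s), error = function(e) NULL)
  })
  token_ok <- !vapply(tokens, is.null, logical(1))
  mols <- vector("list", length(smiles))
  failed <- which(!token_ok)
  ok <- which(token_ok)
  if (length(ok) > 0L) {
    recs <- backend_call(smiles[ok], gen3d = gen3d, seed = seed)
    for (k in seq_along(ok)) {
      i <- ok[k]
      if (is.null(recs[[k]])) {
        failed <- c(failed, i)
      } else {
        val <- tryCatch(
          .mol_from_record(smiles[[i]], tokens[[i]], recs[[k]]),
          error = function(e) NULL)
        if (is.null(val)) failed <- c(failed, i) else mols[[i]] <- val
      }
    }
  }
  list(mols = mols, failed = sort(unique(failed)))
}

#' Parse a SMILES string into a molecule record
#'
#' Parses one raw SMILES string (no canonicalization, no atom renumbering)
#' into a heavy-atom molecule record whose atom order equals the order of
#' atom tokens in the input string - the property the positional readout of
#' the network relies on. Hydrogens stay implicit: they are counted per
#' heavy atom, never given nodes.
#'
#' @param smiles A single SMILES string. Multi-fragment strings (containing
#'   `.`) are rejected: positional readout needs a well-defined last atom.
#' @param gen3d Also build a 3D conformer (seeded distance-geometry
#'   embedding plus force-field relaxation) with partial charges.
#' @param seed Integer seed for the conformer embedding.
#' @return An object of class `molgat_mol`: a list with `atoms` (one row per
#'   heavy atom, SMILES order), `bonds` (1-based heavy-atom index pairs),
#'   `descriptors`, and optionally `geometry` (all-atom coordinates,
#'   partial charges, grid volume).
#' @examples
#' \dontrun{
#' mol <- parse_smiles("CCO")
#' mol$atoms$element   # "C" "C" "O"
#' }
#' @export
parse_smiles <- function(smiles, gen3d = FALSE, seed = 0L) {
  res <- mols_from_smiles(smiles, gen3d = gen3d, seed = seed)
  if (length(res$failed) > 0L || is.null(res$mols[[1L]])) {
    rlang::abort(paste0("SMILES failed to parse: ", smiles),
                 class = "molgat_parse_error")
  }
  res$mols[[1L]]
}

#' @export
print.molgat_mol <- function(x, ...) {
  cat("<molgat_mol> ", x$smiles, "\n", sep = "")
  cat("  heavy atoms: ", nrow(x$atoms), ", bonds: ", nrow(x$bonds),
      if (!is.null(x$geometry)) ", 3D conformer present" else "",
      "\n", sep = "")
  invisible(x)
}
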