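# RDKit subprocess backend.
#
# All chemistry that is not this package's own contribution (SMILES
# sanitization, atom properties, standard descriptors, seeded 3D embedding,
# force-field partial charges, grid-based molecular volume) is delegated to
# RDKit through one batched `python` call per dataset. The worker script
# lives in inst/python/mol_backend.py and speaks JSON over temp files; it
# never reorders atoms, so record i's atom arrays follow the SMILES token
# order of input i.

backend_python <- function() {
  path <- Sys.getenv("MOLGAT_PYTHON", unset = Sys.which("python"))
  if (!nzchar(path)) {
    rlang::abort("python was not found on the PATH; RDKit is required",
                 class = "molgat_backend_error")
  }
  path
}

backend_script <- function() {
  path <- system.file("python", "mol_backend.py", package = "molgat")
  if (!nzchar(path) && file.exists("inst/python/mol_backend.py")) {
    path <- "inst/python/mol_backend.py"
  }
  if (!nzchar(path)) {
    rlang::abort("mol_backend.py not found in the installed package",
                 class = "molgat_backend_error")
  }
  path
}

# One batched RDKit call. Returns a list of length(smiles): NULL for parse
# failures, otherwise a raw molecule record (atom arrays, bond list,
# descriptors, and - when gen3d - a geometry record or error marker).
backend_call <- function(smiles, gen3d = FALSE, seed = 0L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  # identical SMILES give identical records (the conformer seed is shared),
  # so only unique strings cross the process boundary
  uniq <- unique(smiles)
  if (length(uniq) < length(smiles)) {
    recs <- backend_call(uniq, gen3d = gen3d, seed = seed)
    return(recs[match(smiles, uniq)])
  }
  req <- tempfile(fileext = ".json")
  res <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, res)), add = TRUE)
  jsonlite::write_json(
    list(smiles = I(smiles), gen3d = gen3d, seed = seed),
    req, auto_unbox = TRUE)
  status <- suppressWarnings(
    system2(backend_python(), c(shQuote(backend_script()),
                                shQuote(req), shQuote(res)),
            stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(res)) {
    rlang::abort("the RDKit backend process failed",
                 class = "molgat_backend_error")
  }
  jsonlite::fromJSON(res, simplifyVector = FALSE)
}
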