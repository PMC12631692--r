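#' Dataset dialects for benchmark CSV files
#'
#' The public benchmark sets store SMILES and targets under different
#' column names. A dialect names the two columns; the built-ins cover the
#' four benchmark sets (water log-solubility, hydration free energy, logD,
#' pIC50) plus a `generic` smiles/target layout. All are overridable.
#'
#' @param name Dialect name (free text for custom dialects).
#' @param smiles_column,target_column Column names in the CSV header.
#' @return A `molgat_dialect` list.
#' @export
dataset_dialect <- function(name = "generic", smiles_column = NULL,
                            target_column = NULL) {
  builtin <- list(
    esol = list(smiles = "smiles",
                target = "measured log solubility in mols per litre"),
    freesolv = list(smiles = "smiles", target = "expt"),
    lipophilicity = list(smiles = "smiles", target = "exp"),
    bace = list(smiles = "mol", target = "pIC50"),
    generic = list(smiles = "smiles", target = "target"))
  base <- builtin[[name]] %||% builtin$generic
  structure(list(name = name,
                 smiles_column = smiles_column %||% base$smiles,
                 target_column = target_column %||% base$target),
            class = "molgat_dialect")
}

#' Load a SMILES/target dataset from CSV
#'
#' Reads a CSV with a header row and returns one record per parsable row,
#' in file order. The SMILES string is kept byte-identical to the file
#' cell (no canonicalization, no stereochemistry stripping): the raw
#' string is the node-ordering authority for the graphs built later. Rows
#' whose SMILES fails to parse or whose target is non-numeric are dropped
#' with a warning and counted in the `dropped` attribute.
#'
#' @param path CSV file path.
#' @param dialect A [dataset_dialect()] or a built-in dialect name.
#' @return Tibble with columns `smiles`, `target`, `source_row` (1-based
#'   data-row number in the file), `dataset_name`; attributes
#'   `n_dropped_parse`, `n_dropped_target`.
#' @export
load_dataset <- function(path, dialect = "generic") {
  if (is.character(dialect)) dialect <- dataset_dialect(dialect)
  if (!file.exists(path)) {
    rlang::abort(paste0("dataset file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  for (col in c(dialect$smiles_column, dialect$target_column)) {
    if (!col %in% names(raw)) {
      rlang::abort(paste0("column '", col, "' not found in ", path))
    }
  }
  smiles <- raw[[dialect$smiles_column]]
  target <- suppressWarnings(as.numeric(raw[[dialect$target_column]]))
  bad_target <- !is.finite(target) | is.na(smiles) | !nzchar(smiles)
  parse_failed <- rep(FALSE, nrow(raw))
  ok <- which(!bad_target)
  if (length(ok) > 0L) {
    res <- mols_from_smiles(smiles[ok], gen3d = FALSE)
    parse_failed[ok[res$failed]] <- TRUE
  }
  keep <- !bad_target & !parse_failed
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    rlang::warn(paste0(n_drop, " row(s) dropped from ", basename(path),
                       " (", sum(parse_failed), " unparsable SMILES, ",
                       sum(bad_target), " missing/non-numeric target)"))
  }
  out <- tibble::tibble(smiles = smiles[keep], target = target[keep],
                        source_row = which(keep),
                        dataset_name = dialect$name)
  attr(out, "n_dropped_parse") <- sum(parse_failed)
  attr(out, "n_dropped_target") <- sum(bad_target)
  out
}

#' Write records back to a generic-dialect CSV
#'
#' @param data Data frame with `smiles` and `target` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(data[, c("smiles", "target")], path, progress = FALSE)
  invisible(path)
}

#' Drop records whose 3D geometry failed
#'
#' Removes the given records (by position), logging each removed SMILES,
#' and preserves the order of the survivors. This mirrors the pragmatic
#' handling of benchmark molecules for which no conformer or no partial
#' charges can be computed.
#'
#' @param records Tibble of records.
#' @param failures Integer positions (1-based) to remove; may be empty.
#' @return The surviving records.
#' @export
drop_failed_geometry <- function(records, failures) {
  if (length(failures) == 0L) return(records)
  failures <- as.integer(failures)
  if (any(failures < 1L) || any(failures > nrow(records))) {
    rlang::abort("failure index out of range")
  }
  for (i in failures) {
    rlang::inform(paste0("dropping molecule with failed geometry: ",
                         records$smiles[[i]]))
  }
  records[-failures, , drop = FALSE]
}
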