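# Model checkpoints.
#
# Format (version 1): one JSON object with fields `format_version`,
# `config` (the molgat_config minus the readout object, which is stored as
# kind + seed), `dims`, and `layers` - a list of named numeric arrays per
# layer with explicit dimensions, so the file is a flat named-tensor
# archive in plain text. Values survive the decimal round-trip to
# ~1e-15 relative precision (not bit-exact).

.checkpoint_version <- 1L

#' Save a model or fit to a JSON checkpoint
#'
#' @param model A `molgat_model` or `molgat_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "molgat_fit")) model <- model$model
  stopifnot(inherits(model, "molgat_model"))
  cfg <- model$config
  payload <- list(
    format_version = .checkpoint_version,
    config = list(layer_type = cfg$layer_type, n_layers = cfg$n_layers,
                  hidden = cfg$hidden, n_features = cfg$n_features,
                  readout_kind = cfg$readout$kind,
                  readout_seed = cfg$readout$seed, seed = cfg$seed),
    dims = model$dims,
    layers = lapply(model$layers, function(l) {
      tensors <- lapply(l[setdiff(names(l), "type")], function(p) {
        list(dim = if (is.matrix(p)) dim(p) else length(p),
             data = as.numeric(p))
      })
      c(list(type = l$type), tensors)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model from a JSON checkpoint
#'
#' @param path Checkpoint written by [save_model()].
#' @return A `molgat_model` identical to the saved one.
#' @export
load_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(as.integer(payload$format_version),
                 .checkpoint_version)) {
    rlang::abort(paste0("unsupported checkpoint format version: ",
                        payload$format_version))
  }
  cfg <- payload$config
  config <- model_config(
    layer_type = cfg$layer_type, n_layers = cfg$n_layers,
    hidden = cfg$hidden, n_features = cfg$n_features,
    readout = readout_strategy(cfg$readout_kind, seed = cfg$readout_seed),
    seed = cfg$seed)
  model <- build_model(config)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)$layers
  model$layers <- lapply(raw, function(l) {
    out <- list(type = l$type)
    for (nm in setdiff(names(l), "type")) {
      d <- unlist(l[[nm]]$dim)
      x <- as.numeric(unlist(l[[nm]]$data))
      out[[nm]] <- if (length(d) == 2L) matrix(x, d[1L], d[2L]) else x
    }
    out
  })
  model
}

#' Dump a graph as edge-list text
#'
#' Debug helper: writes one `i j` pair per line (1-based SMILES positions)
#' with a `# smiles n_nodes` header line.
#'
#' @param graph A `molgat_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "molgat_graph"))
  lines <- c(paste("#", graph$smiles, graph$n_nodes),
             apply(graph$edges, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
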