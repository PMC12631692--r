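#' Scan the atom tokens of a SMILES string
#'
#' Walks a SMILES string left to right and returns one row per atom token,
#' in the order encountered. This order is the node-ordering authority for
#' the whole package: node `i` of a molecular graph is the `i`-th atom token
#' of the raw input SMILES (ring-closure digits, bond symbols and branch
#' parentheses do not create atoms). Bracket atoms are decomposed into
#' isotope, element, explicit hydrogen count and formal charge.
#'
#' @param smiles A single SMILES string.
#' @return A tibble with one row per atom token and columns
#'   `position` (1-based atom index), `token` (the raw token text),
#'   `element` (capitalized symbol), `aromatic` (lowercase-form flag),
#'   `bracket` (was the atom written in brackets), `explicit_h`
#'   (bracket H count, `NA` for non-bracket atoms), `formal_charge`
#'   and `isotope` (`NA` when unspecified).
#' @examples
#' \dontrun{
#' smiles_atom_tokens("CC(=O)[O-]")
#' }
#' @export
smiles_atom_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  if (grepl(".", smiles, fixed = TRUE)) {
    rlang::abort(
      paste0("multi-fragment SMILES (contains '.') are not supported: ",
             smiles),
      class = "molgat_multifragment_error")
  }
  # Atom tokens: bracket atoms, two-letter organic-subset halogens, then
  # one-letter organic-subset atoms (aromatic forms included).
  pat <- "\\[[^]]*\\]|Cl|Br|[BCNOPSFI]|[bcnops]"
  m <- gregexpr(pat, smiles)[[1]]
  if (m[1] == -1L) {
    rlang::abort(paste0("no atom tokens found in SMILES: ", smiles),
                 class = "molgat_parse_error")
  }
  tokens <- regmatches(smiles, gregexpr(pat, smiles))[[1]]
  rows <- purrr::imap(tokens, function(tok, i) {
    if (startsWith(tok, "[")) {
      inner <- substr(tok, 2L, nchar(tok) - 1L)
      mm <- regexec(
        "^([0-9]*)([A-Z][a-z]?|[bcnops]|se|as)(@{1,2}|@TH[12])?(H[0-9]*)?(\\+{1,}[0-9]*|-{1,}[0-9]*)?(:[0-9]+)?$",
        inner)
      parts <- regmatches(inner, mm)[[1]]
      if (length(parts) == 0L) {
        rlang::abort(paste0("cannot parse bracket atom ", tok),
                     class = "molgat_parse_error")
      }
      iso <- if (nzchar(parts[2])) as.integer(parts[2]) else NA_integer_
      el <- parts[3]
      aromatic <- el == tolower(el)
      hpart <- parts[5]
      h <- if (!nzchar(hpart)) 0L
           else if (hpart == "H") 1L
           else as.integer(substr(hpart, 2L, nchar(hpart)))
      cpart <- parts[6]
      charge <- 0L
      if (nzchar(cpart)) {
        sign <- if (startsWith(cpart, "+")) 1L else -1L
        digits <- gsub("[+-]", "", cpart)
        n_signs <- nchar(gsub("[^+-]", "", cpart))
        charge <- if (nzchar(digits)) sign * as.integer(digits)
                  else sign * n_signs
      }
      el_cap <- paste0(toupper(substr(el, 1L, 1L)),
                       substring(el, 2L))
      tibble::tibble(position = i, token = tok, element = el_cap,
                     aromatic = aromatic, bracket = TRUE,
                     explicit_h = h, formal_charge = charge,
                     isotope = iso)
    } else {
      aromatic <- tok == tolower(tok)
      el_cap <- paste0(toupper(substr(tok, 1L, 1L)), substring(tok, 2L))
      tibble::tibble(position = i, token = tok, element = el_cap,
                     aromatic = aromatic, bracket = FALSE,
                     explicit_h = NA_integer_, formal_charge = 0L,
                     isotope = NA_integer_)
    }
  })
  dplyr::bind_rows(rows)
}
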