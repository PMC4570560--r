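## Shared helpers: typed error conditions, site keys, residue parsing,
## seed substreams.

silac_abort <- function(class, msg) {
  cond <- structure(
    class = c(class, "silacsites_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

config_error    <- function(msg) silac_abort("silac_config_error", msg)
format_error    <- function(msg) silac_abort("silac_format_error", msg)
statistic_error <- function(msg) silac_abort("silac_statistic_error", msg)
value_error     <- function(msg) silac_abort("silac_value_error", msg)

#' Build the join key for a phosphosite
#'
#' Cross-table joins (site table vs. kinase-substrate table vs. truth table)
#' are keyed by the uppercased gene symbol plus the residue string, e.g.
#' `"EGFR_T695"`, because public kinase-substrate resources key substrates
#' by gene and residue rather than by protein accession.
#'
#' @param gene character vector of gene symbols.
#' @param residue character vector of residue strings such as `"T695"`.
#' @return character vector of keys.
#' @export
#' @examples
#' site_key("Egfr", "T695")
site_key <- function(gene, residue) {
  paste(toupper(gene), residue, sep = "_")
}

#' Parse phosphosite residue strings
#'
#' A residue string is a single amino-acid letter in `{S, T, Y}` followed by a
#' 1-based integer position, e.g. `"Y1197"`. Parsing and [format_residue()]
#' are inverse bijections on the set of valid strings.
#'
#' @param x character vector of residue strings.
#' @return data.frame with columns `aa` (character) and `pos` (integer);
#'   invalid entries yield `NA` in both columns.
#' @export
#' @examples
#' parse_residue(c("T695", "S9", "x1"))
parse_residue <- function(x) {
  ok <- is_valid_residue(x)
  aa <- ifelse(ok, substr(x, 1L, 1L), NA_character_)
  pos <- rep(NA_integer_, length(x))
  pos[ok] <- as.integer(substring(x[ok], 2L))
  data.frame(aa = aa, pos = pos, stringsAsFactors = FALSE)
}

#' @rdname parse_residue
#' @param aa amino-acid letter, one of `"S"`, `"T"`, `"Y"`.
#' @param pos 1-based integer position.
#' @export
format_residue <- function(aa, pos) {
  stopifnot(all(aa %in% c("S", "T", "Y")), all(pos >= 1L))
  paste0(aa, as.integer(pos))
}

#' @rdname parse_residue
#' @export
is_valid_residue <- function(x) {
  !is.na(x) & grepl("^[STY][1-9][0-9]*$", x)
}

## Deterministic 32-bit sub-seed for independent generator substreams, so
## regenerating one synthetic table never perturbs another.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65536 * 32003 + k * 7919 + 17) %% 2147483647)
}
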