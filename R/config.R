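#' Load the domain-signature configuration
#'
#' Reads the YAML table of anchor motifs, window widths, catalytic-residue
#' rules, AT substrate-specificity patterns, KR typing rules and the
#' docking-domain heuristic parameters. The shipped default encodes the
#' standard cis-AT conventions (GHSxG acyltransferase active site with a
#' YASH/HAFH specificity window; (L/V)D(D/N) B-type ketoreductase motif).
#' All rules are data, not code: point `path` at an edited copy to swap in
#' alternative residue sets.
#'
#' @param path Path to a YAML file; `NULL` loads the packaged default.
#' @return A nested list with components `domains`, `at`, `kr`, `docking`.
#' @export
#' @examples
#' cfg <- load_signature_config()
#' names(cfg$domains)
load_signature_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "signatures.yaml", package = "pksline")
  }
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$domains), is.list(cfg$at), is.list(cfg$kr),
            is.list(cfg$docking))
  cfg
}

#' Load the chemistry configuration
#'
#' Monoisotopic element masses, adduct definitions, the starter-unit
#' library and protecting-group formula deltas used by the backbone and
#' mass operations.
#'
#' @param path Path to a YAML file; `NULL` loads the packaged default.
#' @return A nested list with components `element_masses`, `adducts`,
#'   `starters`, `protecting_groups`, `default_protecting_group`.
#' @export
load_chem_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chem.yaml", package = "pksline")
  }
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$element_masses), is.list(cfg$adducts),
            is.list(cfg$starters))
  cfg
}

# Stable short hash of a config list, recorded in report provenance.
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg, control = "all"), collapse = "\n")
  # rolling polynomial hash over the serialized text; enough to detect edits
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
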