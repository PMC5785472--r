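# Compare an assembly line against a target product specification,
# quantify module deficits, search a genome for trans-acting module
# candidates, and enumerate programmed-iteration hypotheses by
# exhaustive two-pass simulation.

#' Read a product specification
#'
#' Product specs are structured YAML: name, molecular formula, macrolactam
#' ring size, starter unit, the per-extension target unit states, the
#' methylmalonyl branch positions, carbon-label annotations and the
#' tailoring event list. The shipped sceliphrolactam spec is loaded with
#' [sceliphrolactam_spec()].
#'
#' @param path YAML file path.
#' @param chem Chemistry configuration (starter library).
#' @return A `product_spec`: list with `name`, `formula`
#'   (`chem_formula`), `ring_size`, `starter` (`starter_unit`),
#'   `target_units` (data frame), `branch_positions`,
#'   `position_annotations`, `tailoring`.
#' @export
read_product_spec <- function(path, chem = load_chem_config()) {
  y <- yaml::read_yaml(path)
  starter <- starter_unit(y$starter, chem)
  units <- do.call(rbind, lapply(y$target_units, function(u)
    data.frame(position = as.integer(u$position), alpha = u$alpha,
               beta = u$beta, stereo = u$stereo %||% "none",
               geometry = u$geometry %||% "none",
               stringsAsFactors = FALSE)))
  units <- units[order(units$position), , drop = FALSE]
  rownames(units) <- NULL
  spec <- structure(list(
    name = y$name, formula = chem_formula(y$formula),
    ring_size = as.integer(y$ring_size), starter = starter,
    target_units = units,
    branch_positions = as.integer(unlist(y$branch_positions)),
    position_annotations = y$position_annotations,
    tailoring = y$tailoring), class = "product_spec")
  validate_product_spec(spec)
  spec
}

validate_product_spec <- function(spec) {
  R <- spec$ring_size; A <- spec$starter$ring_atoms
  if ((R - A) %% 2L != 0L) {
    stop("inconsistent product spec: ring size minus starter ring atoms ",
         "must be even")
  }
  E <- (R - A) %/% 2L
  if (E < 1L) stop("product spec implies no chain extensions")
  if (nrow(spec$target_units) != E) {
    stop(sprintf("target_units has %d rows but (R - A)/2 = %d",
                 nrow(spec$target_units), E))
  }
  n_ch3 <- sum(spec$target_units$alpha == "CH3")
  if (length(spec$branch_positions) != n_ch3 ||
      !all(spec$target_units$alpha[spec$branch_positions] == "CH3")) {
    stop("branch_positions must list exactly the CH3 alpha positions")
  }
  invisible(spec)
}

#' The shipped sceliphrolactam product specification
#'
#' 26-membered polyene macrolactam on a 3-amino-2-methylpropionate
#' starter; eleven extensions (nine malonyl, two methylmalonyl at
#' positions 3 and 9), molecular formula C28H35NO6 after tailoring. The
#' per-extension unit states are a figure-derived reconstruction of the
#' published structure (see the shipped YAML for the annotation).
#'
#' @param chem Chemistry configuration.
#' @return A `product_spec`.
#' @export
sceliphrolactam_spec <- function(chem = load_chem_config()) {
  read_product_spec(system.file("extdata", "sceliphrolactam.yaml",
                                package = "pksline"), chem)
}

#' @export
print.product_spec <- function(x, ...) {
  cat(sprintf(
    "<product_spec> %s: %s, %d-membered ring, starter %s, %d extensions\n",
    x$name, format(x$formula), x$ring_size, x$starter$name,
    nrow(x$target_units)))
  invisible(x)
}

#' Build a product spec directly from unit states
#'
#' Convenience constructor for audits against a known backbone (e.g. the
#' truth record of a synthetic fixture): the ring size, branch positions
#' and formula are derived from the unit table.
#'
#' @param name Product name.
#' @param starter A `starter_unit`.
#' @param units Data frame of unit states (`position`, `alpha`, `beta`,
#'   optionally `stereo`, `geometry`).
#' @param tailoring Optional tailoring event list.
#' @return A `product_spec`.
#' @export
product_spec_from_units <- function(name, starter, units,
                                    tailoring = list()) {
  bb <- backbone_from_units(starter, units)
  bb$amine_protected <- FALSE
  bb <- macrolactamize(bb)
  spec <- structure(list(
    name = name, formula = molecular_formula(bb),
    ring_size = bb$ring_size, starter = starter,
    target_units = bb$units,
    branch_positions = which(bb$units$alpha == "CH3"),
    position_annotations = list(), tailoring = tailoring),
    class = "product_spec")
  validate_product_spec(spec)
  spec
}

#' Required chain extensions of a product spec
#'
#' From the collinearity arithmetic: E_req = (R - A) / 2 where R is the
#' macrolactam ring size and A the starter's ring-atom count. The
#' extender split follows the branch positions: methylmalonyl
#' ("propionyl-derived") units carry the alpha-methyls, the rest are
#' malonyl ("acetyl-derived").
#'
#' @param spec A `product_spec`.
#' @return List with `E_req`, `n_malonyl`, `n_methylmalonyl`.
#' @export
#' @examples
#' required_extensions(sceliphrolactam_spec())  # 11 = 9 + 2
required_extensions <- function(spec) {
  stopifnot(inherits(spec, "product_spec"))
  validate_product_spec(spec)
  E <- (spec$ring_size - spec$starter$ring_atoms) %/% 2L
  n_mm <- length(spec$branch_positions)
  list(E_req = E, n_malonyl = E - n_mm, n_methylmalonyl = n_mm)
}

# Predicted unit-state table for a module list (normal, single-pass).
predicted_units <- function(modules) {
  do.call(rbind, lapply(seq_along(modules), function(i) {
    u <- module_unit(modules[[i]])
    data.frame(position = i, alpha = u$alpha, beta = u$beta,
               stereo = u$stereo, geometry = u$geometry,
               stringsAsFactors = FALSE)
  }))
}

units_equal <- function(a, b, granularity = c("state", "strict")) {
  granularity <- match.arg(granularity)
  if (nrow(a) != nrow(b)) return(FALSE)
  ok <- all(a$alpha == b$alpha) && all(a$beta == b$beta)
  if (granularity == "strict") {
    ok <- ok && all(a$stereo == b$stereo) && all(a$geometry == b$geometry)
  }
  ok
}

#' Audit an assembly line against a product specification
#'
#' Computes the module deficit D = E_req - M_enc between the extensions
#' the product demands and the extension modules the cluster encodes.
#' When D = 0 the predicted per-position unit states are compared with
#' the target; when D != 0 the positional comparison is deferred to
#' hypothesis search.
#'
#' @param line An `assembly_line`.
#' @param spec A `product_spec`.
#' @param granularity `"state"` compares alpha substituent and beta state
#'   only (default; stereochemistry is motif-assigned, not
#'   iteration-logic); `"strict"` also compares stereo and geometry.
#' @return An `audit_report`: list with `E_req`, `M_enc`, `deficit`,
#'   `verdict` (`collinear`/`deficit`/`excess`/`mismatch`),
#'   `match_table` (data frame or `NULL`), `granularity`.
#' @export
audit_collinearity <- function(line, spec,
                               granularity = c("state", "strict")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(line, "assembly_line"),
            inherits(spec, "product_spec"))
  req <- required_extensions(spec)
  ext <- extension_modules(line)
  M <- length(ext)
  D <- req$E_req - M
  match_table <- NULL
  if (D == 0L) {
    pred <- predicted_units(ext)
    tgt <- spec$target_units
    match_table <- data.frame(
      position = tgt$position,
      target_alpha = tgt$alpha, predicted_alpha = pred$alpha,
      target_beta = tgt$beta, predicted_beta = pred$beta,
      match = tgt$alpha == pred$alpha & tgt$beta == pred$beta,
      stringsAsFactors = FALSE)
    if (granularity == "strict") {
      match_table$match <- match_table$match &
        tgt$stereo == pred$stereo & tgt$geometry == pred$geometry
    }
    verdict <- if (all(match_table$match)) "collinear" else "mismatch"
  } else {
    verdict <- if (D > 0L) "deficit" else "excess"
  }
  structure(list(E_req = req$E_req, M_enc = M, deficit = D,
                 verdict = verdict, match_table = match_table,
                 granularity = granularity, product = spec$name),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf(
    "<audit_report> %s: requires %d extensions, cluster encodes %d\n",
    x$product, x$E_req, x$M_enc))
  cat(sprintf("  deficit D = %d -> verdict: %s\n", x$deficit, x$verdict))
  if (!is.null(x$match_table) && !all(x$match_table$match)) {
    cat("  mismatched positions:",
        paste(x$match_table$position[!x$match_table$match],
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Search a genome for trans-acting module candidates
#'
#' Scans every gene outside the audited cluster for a stand-alone PKS
#' module with exactly the required domain composition (default
#' KS-AT-ACP, the composition a non-reducing trans module must have) and,
#' when `require_docking`, docking domains at both termini so the module
#' could insert into the assembly-line complex.
#'
#' @param genome_genes A [pks_genes] data frame of candidate genes (the
#'   audited cluster's genes excluded by the caller).
#' @param required_composition Character vector of domain classes.
#' @param require_docking Require docking ends at both termini.
#' @param config Signature configuration.
#' @return List of `hypothesis` objects (`kind = "trans_module"`,
#'   `consistent = FALSE` until backbone-checked); empty when no
#'   candidate survives.
#' @export
find_trans_candidates <- function(genome_genes,
                                  required_composition = c("KS", "AT",
                                                           "ACP"),
                                  require_docking = TRUE,
                                  config = load_signature_config()) {
  stopifnot(inherits(genome_genes, "pks_genes"))
  out <- list()
  for (i in seq_len(nrow(genome_genes))) {
    seqi <- genome_genes$protein[i]
    if (nchar(seqi) < 50) next
    hits <- scan_domains(seqi, config = config)
    if (!identical(hits$domain_class, required_composition)) next
    if (require_docking) {
      dock <- detect_docking(seqi, hits, config)
      if (!dock$N$present || !dock$C$present) next
    }
    out[[length(out) + 1L]] <- structure(
      list(kind = "trans_module",
           gene_id = genome_genes$gene_id[i], module_index = NA_integer_,
           pass_states = NULL, resulting_backbone = NULL,
           consistent = FALSE),
      class = "pks_hypothesis")
  }
  out
}

# Simulate the E_req-extension unit table obtained when module m of the
# line runs twice with per-pass active reductive-domain sets S1 and S2.
simulate_two_pass <- function(ext, m, s1, s2) {
  states <- vector("list", length(ext) + 1L)
  j <- 0L
  for (i in seq_along(ext)) {
    if (i == m) {
      j <- j + 1L; states[[j]] <- module_unit(ext[[i]], override_active = s1)
      j <- j + 1L; states[[j]] <- module_unit(ext[[i]], override_active = s2)
    } else {
      j <- j + 1L; states[[j]] <- module_unit(ext[[i]])
    }
  }
  do.call(rbind, lapply(seq_along(states), function(p)
    data.frame(position = p, alpha = states[[p]]$alpha,
               beta = states[[p]]$beta, stereo = states[[p]]$stereo,
               geometry = states[[p]]$geometry, stringsAsFactors = FALSE)))
}

all_subsets <- function(x) {
  if (length(x) == 0L) return(list(character(0)))
  out <- list(character(0))
  for (el in x) out <- c(out, lapply(out, function(s) c(s, el)))
  out[order(vapply(out, length, 0L),
            vapply(out, function(s) paste(sort(s), collapse = "+"), ""))]
}

subset_label <- function(s) {
  if (length(s) == 0L) return("(none)")
  paste(sort(s), collapse = "+")
}

#' Enumerate programmed-iteration hypotheses for a one-module deficit
#'
#' Exhaustive two-pass search: for every extension module m and every
#' ordered pair (S1, S2) of activity subsets of m's reductive domains
#' (KR/DH/ER toggles; the AT class is fixed, and a pass can only switch
#' OFF domains the protein physically carries), the
#' E_req-extension backbone [1..m with S1, m again with S2, m+1..] is
#' simulated and kept when it reproduces the target unit states.
#' Hypotheses with identical resulting backbones for the same module are
#' collapsed; results are ordered by module index, then pass states.
#' Only the single-deficit case is implemented; D >= 2 raises a
#' not-implemented error.
#'
#' @param line An `assembly_line` whose audit deficit is exactly 1.
#' @param spec A `product_spec`.
#' @param granularity Unit comparison granularity, see
#'   [audit_collinearity()].
#' @return List of `hypothesis` objects (`kind = "iterative"`), each with
#'   `gene_id`, `module_index`, `pass_states` (two character vectors of
#'   active reductive domains), `toggled` (domains whose activity differs
#'   between passes), `resulting_backbone` (unit-state data frame),
#'   `consistent = TRUE`.
#' @export
enumerate_iterative_hypotheses <- function(line, spec,
                                           granularity = c("state",
                                                           "strict")) {
  granularity <- match.arg(granularity)
  audit <- audit_collinearity(line, spec, granularity)
  if (audit$deficit != 1L) {
    stop("iterative-module search is implemented for a deficit of ",
         "exactly 1 (audit deficit: ", audit$deficit, ")")
  }
  ext <- extension_modules(line)
  tgt <- spec$target_units
  out <- list()
  for (m in seq_along(ext)) {
    red <- sort(intersect(ext[[m]]$domains$domain_class,
                          c("KR", "DH", "ER")))
    subsets <- all_subsets(red)
    seen <- character()
    for (s1 in subsets) {
      for (s2 in subsets) {
        sim <- simulate_two_pass(ext, m, s1, s2)
        if (!units_equal(sim, tgt, granularity)) next
        key <- paste(sim$alpha, sim$beta, sim$stereo, sim$geometry,
                     collapse = ";")
        if (key %in% seen) next  # same module, same resulting backbone
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- structure(
          list(kind = "iterative", gene_id = ext[[m]]$gene_id,
               module_index = ext[[m]]$module_index,
               pass_states = list(pass1 = s1, pass2 = s2),
               toggled = union(setdiff(s1, s2), setdiff(s2, s1)),
               resulting_backbone = sim, consistent = TRUE),
          class = "pks_hypothesis")
      }
    }
  }
  out
}

#' @export
print.pks_hypothesis <- function(x, ...) {
  if (x$kind == "iterative") {
    cat(sprintf(
      "<hypothesis> iterative: %s module %d, pass1 %s / pass2 %s (toggled: %s)\n",
      x$gene_id, x$module_index, subset_label(x$pass_states$pass1),
      subset_label(x$pass_states$pass2),
      if (length(x$toggled)) paste(x$toggled, collapse = ", ")
      else "none"))
  } else {
    cat(sprintf("<hypothesis> trans module candidate: gene %s\n",
                x$gene_id))
  }
  invisible(x)
}
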