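# Predict the polyketide backbone from an assembly line and a starter
# unit, macrolactamize, apply declarative tailoring events, and compute
# molecular formula, degrees of unsaturation, monoisotopic mass and
# adduct m/z from an explicit atom ledger.

BETA_STATES <- c("ketone", "hydroxyl", "enoyl", "methylene")

#' Look up a starter unit
#'
#' Starter units are beta-amino-acid primers whose amine closes the
#' macrolactam. `ring_atoms` counts the atoms the starter contributes to
#' the ring, including the amide nitrogen (4 for
#' 3-amino-2-methylpropionate).
#'
#' @param name Entry in the starter library of the chemistry config.
#' @param chem Chemistry configuration, see [load_chem_config()].
#' @return A `starter_unit`: list with `name`, `ring_atoms`,
#'   `alpha_methyl`, `methyl_branches`, `amine_protected`,
#'   `formula_contribution`.
#' @export
starter_unit <- function(name, chem = load_chem_config()) {
  entry <- chem$starters[[name]]
  if (is.null(entry)) {
    stop("unknown starter unit: ", name, " (library: ",
         paste(names(chem$starters), collapse = ", "), ")")
  }
  A <- as.integer(entry$ring_atoms)
  if (A < 2L) stop("starter must contribute at least 2 ring atoms")
  nme <- as.integer(entry$methyl_branches %||% as.integer(entry$alpha_methyl))
  # ring carbons = A - 1 (the nitrogen is the A-th ring atom); default
  # chain carbons carry 2 H except the carboxyl-derived carbon whose
  # H/O bookkeeping belongs to extension 1's beta state
  contrib <- c(C = (A - 1L) + nme,
               H = 2L * (A - 2L) + 1L + 2L * nme,
               N = 1L)
  structure(list(name = name, ring_atoms = A,
                 alpha_methyl = isTRUE(entry$alpha_methyl),
                 methyl_branches = nme,
                 amine_protected = isTRUE(entry$amine_protected),
                 formula_contribution = contrib),
            class = "starter_unit")
}

# Shared module -> unit rule: alpha substituent from the AT call, beta
# state from which reductive domains are present AND active. `active`
# is a character vector naming the reductive domains acting in this pass.
unit_from_activity <- function(at_substrate, active, kr_stereo = "none") {
  alpha <- if (identical(at_substrate, "methylmalonyl")) "CH3" else "H"
  if (!"KR" %in% active) {
    list(alpha = alpha, beta = "ketone", stereo = "none", geometry = "none")
  } else if (!"DH" %in% active) {
    list(alpha = alpha, beta = "hydroxyl", stereo = kr_stereo,
         geometry = "none")
  } else if (!"ER" %in% active) {
    list(alpha = alpha, beta = "enoyl", stereo = "none", geometry = "E")
  } else {
    list(alpha = alpha, beta = "methylene", stereo = "none",
         geometry = "none")
  }
}

# Reductive domains of a module that are present and catalytically active.
active_reductive <- function(module) {
  red <- intersect(module$domains$domain_class, c("KR", "DH", "ER"))
  ok <- vapply(red, function(cls) {
    i <- match(cls, module$domains$domain_class)
    act <- module$activity[[i]]
    isTRUE(act$active) &&
      !(cls == "KR" && !is.null(module$kr_call) &&
          module$kr_call$kr_type == "inactive")
  }, logical(1))
  red[ok]
}

module_unit <- function(module, override_active = NULL,
                        geometry_override = NULL) {
  if (is.null(module$at_call) ||
      identical(module$at_call$substrate, "unknown")) {
    stop(sprintf(
      "module %d (%s) has an unknown AT substrate; override the call ",
      module$module_index, module$gene_id),
      "in configuration before predicting a backbone")
  }
  active <- if (is.null(override_active)) active_reductive(module)
            else override_active
  stereo <- if (!is.null(module$kr_call) &&
                module$kr_call$kr_type %in% c("A", "B"))
    module$kr_call$beta_oh_config else "none"
  u <- unit_from_activity(module$at_call$substrate, active, stereo)
  if (!is.null(geometry_override) && u$beta == "enoyl") {
    u$geometry <- geometry_override
  }
  u
}

#' Predict the polyketide backbone of an assembly line
#'
#' Extension unit i derives from extension module i: the alpha
#' substituent is CH3 iff the AT call is methylmalonyl; the beta-keto
#' group of the growing chain is left as a ketone when no active KR is
#' present, reduced to a hydroxyl by KR alone (R-configured for B-type,
#' S for A-type), dehydrated to an enoyl by KR+DH (E geometry unless
#' overridden per position), and fully reduced to a methylene by
#' KR+DH+ER. The backbone is returned uncyclized.
#'
#' @param line An `assembly_line` with at least one extension module.
#' @param starter A `starter_unit`.
#' @param geometry_overrides Optional named vector mapping extension
#'   positions to `"E"`/`"Z"` for enoyl units (double-bond geometry is
#'   not predictable from domain content alone).
#' @return A `pks_backbone`: list with `starter`, `units` (data frame:
#'   position, alpha, beta, stereo, geometry, module_index, gene_id),
#'   `ring_size = NULL`, `tailoring = list()`, `amine_protected`.
#' @export
predict_backbone <- function(line, starter, geometry_overrides = NULL) {
  stopifnot(inherits(line, "assembly_line"),
            inherits(starter, "starter_unit"))
  ext <- extension_modules(line)
  if (length(ext) == 0L) stop("assembly line has no extension modules")
  units <- lapply(seq_along(ext), function(i) {
    go <- if (!is.null(geometry_overrides) &&
              as.character(i) %in% names(geometry_overrides))
      geometry_overrides[[as.character(i)]] else NULL
    u <- module_unit(ext[[i]], geometry_override = go)
    data.frame(position = i, alpha = u$alpha, beta = u$beta,
               stereo = u$stereo, geometry = u$geometry,
               module_index = ext[[i]]$module_index,
               gene_id = ext[[i]]$gene_id, stringsAsFactors = FALSE)
  })
  new_backbone(starter, do.call(rbind, units))
}

new_backbone <- function(starter, units, ring_size = NULL,
                         tailoring = list(),
                         amine_protected = starter$amine_protected) {
  stopifnot(all(units$beta %in% BETA_STATES),
            identical(units$position, seq_len(nrow(units))))
  # stereo only on hydroxyls, geometry only on enoyls
  stopifnot(all((units$stereo != "none") == (units$beta == "hydroxyl" &
                                               units$stereo != "none")))
  units$stereo[units$beta != "hydroxyl"] <- "none"
  units$geometry[units$beta != "enoyl"] <- "none"
  structure(list(starter = starter, units = units, ring_size = ring_size,
                 tailoring = tailoring, amine_protected = amine_protected),
            class = "pks_backbone")
}

#' Assemble a backbone directly from unit states
#'
#' Convenience constructor used by product specifications and tests: the
#' per-extension states are given explicitly instead of being derived
#' from an assembly line.
#'
#' @param starter A `starter_unit`.
#' @param units Data frame with columns `position`, `alpha`
#'   (`"H"`/`"CH3"`), `beta` (ketone/hydroxyl/enoyl/methylene) and
#'   optionally `stereo`, `geometry`.
#' @return A `pks_backbone`.
#' @export
backbone_from_units <- function(starter, units) {
  units$position <- as.integer(units$position)
  units <- units[order(units$position), , drop = FALSE]
  if (is.null(units$stereo)) units$stereo <- "none"
  if (is.null(units$geometry)) units$geometry <- "none"
  units$stereo[is.na(units$stereo)] <- "none"
  units$geometry[is.na(units$geometry)] <- "none"
  rownames(units) <- NULL
  new_backbone(starter, units)
}

#' Macrolactamize a backbone
#'
#' Ring closure of the chain carboxyl onto the starter amine. With E
#' extension units contributing two ring atoms each and a starter
#' contributing A ring atoms (amide nitrogen included), the macrolactam
#' ring size is R = 2E + A (26 for E = 11, A = 4).
#'
#' @param backbone A `pks_backbone`.
#' @return The backbone with `ring_size` set.
#' @export
macrolactamize <- function(backbone) {
  stopifnot(inherits(backbone, "pks_backbone"))
  E <- nrow(backbone$units)
  if (E == 0L) stop("cannot cyclize a backbone with no extension units")
  if (backbone$starter$ring_atoms < 2L) {
    stop("starter does not provide a ring-forming amine")
  }
  backbone$ring_size <- 2L * E + backbone$starter$ring_atoms
  backbone
}

#' Apply tailoring events to a backbone
#'
#' Tailoring is declarative: each event applies once and records its
#' formula delta. `hydroxylation` adds exactly one oxygen (a C-H becomes
#' C-OH; the hydrogen count is unchanged). `amide_deprotection` removes
#' the configured protecting-group delta from the starter amide.
#' Duplicate events at the same site are an error.
#'
#' @param backbone A `pks_backbone`.
#' @param events List of events, each a list with `kind`
#'   (`"hydroxylation"` or `"amide_deprotection"`), `site` (carbon
#'   label), `agent` (gene id).
#' @return The backbone with events recorded.
#' @export
apply_tailoring <- function(backbone, events) {
  stopifnot(inherits(backbone, "pks_backbone"))
  for (ev in events) {
    stopifnot(ev$kind %in% c("hydroxylation", "amide_deprotection"))
    prev <- vapply(backbone$tailoring, function(e)
      identical(e$kind, ev$kind) && identical(e$site, ev$site),
      logical(1))
    if (any(prev)) {
      stop("duplicate tailoring event at site ", ev$site)
    }
    if (ev$kind == "amide_deprotection") {
      if (!backbone$amine_protected) {
        stop("amide_deprotection on an unprotected starter amine")
      }
      backbone$amine_protected <- FALSE
    }
    backbone$tailoring <- c(backbone$tailoring, list(ev))
  }
  backbone
}

# ---- formulas -------------------------------------------------------------

#' Construct a molecular formula
#'
#' @param ... Named integer element counts, e.g. `chem_formula(C = 28,
#'   H = 35, N = 1, O = 6)`, or a single named vector/list.
#' @return A `chem_formula`: named integer vector of non-negative counts.
#' @export
chem_formula <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.list(args[[1]]) || length(args[[1]]) > 1L ||
         !is.null(names(args[[1]])))) {
    args <- as.list(args[[1]])
  }
  counts <- vapply(args, function(v) as.integer(round(as.numeric(v))),
                   integer(1))
  if (any(counts < 0L)) stop("negative element count in formula")
  counts <- counts[counts > 0L]
  ord <- c("C", "H", intersect(sort(names(counts)),
                               setdiff(names(counts), c("C", "H"))))
  counts <- counts[intersect(ord, names(counts))]
  structure(counts, class = "chem_formula")
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("(empty)")
  paste0(names(x),
         vapply(unclass(x), function(v)
           if (v > 1L) as.character(v) else "", ""),
         collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", format(x), "\n")
  invisible(x)
}

formula_add <- function(a, b, sign = 1L) {
  els <- union(names(a), names(b))
  out <- setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] + sign * unlist(b)[names(b)]
  if (any(out < 0L)) {
    stop("negative element count (inconsistent tailoring deltas)")
  }
  chem_formula(out)
}

#' Degrees of unsaturation of a formula
#'
#' DBE = C - H/2 + N/2 + 1 (halogen-free, oxygen-neutral convention).
#'
#' @param formula A `chem_formula`.
#' @return Numeric DBE (integer for valid neutral molecules).
#' @export
dbe <- function(formula) {
  g <- function(el) if (el %in% names(formula)) formula[[el]] else 0L
  g("C") - g("H") / 2 + g("N") / 2 + 1
}

#' Molecular formula of a cyclized backbone
#'
#' Assembled from an explicit atom ledger: starter ring atoms and
#' branches, two carbons per extension with alpha hydrogens adjusted for
#' methyl branches and enoyl double bonds, per-beta-state oxygen and
#' hydrogen contributions (ketone: +O; hydroxyl: +O +2H; enoyl: +1H;
#' methylene: +2H), the amide carbonyl oxygen counted once at ring
#' closure, hydroxylation deltas from tailoring, and the protecting-group
#' delta while the starter amide is still protected.
#'
#' @param backbone A cyclized `pks_backbone`.
#' @param chem Chemistry configuration.
#' @return A `chem_formula`.
#' @export
molecular_formula <- function(backbone, chem = load_chem_config()) {
  stopifnot(inherits(backbone, "pks_backbone"))
  if (is.null(backbone$ring_size)) {
    stop("backbone must be cyclized first (see macrolactamize())")
  }
  u <- backbone$units
  C <- backbone$starter$formula_contribution[["C"]]
  H <- backbone$starter$formula_contribution[["H"]]
  N <- backbone$starter$formula_contribution[["N"]]
  O <- 1L  # amide carbonyl, counted once at cyclization
  for (i in seq_len(nrow(u))) {
    C <- C + 2L + (u$alpha[i] == "CH3")
    H <- H + 2L - (u$alpha[i] == "CH3") - (u$beta[i] == "enoyl") +
      c(ketone = 0L, hydroxyl = 2L, enoyl = 1L, methylene = 2L)[[u$beta[i]]]
    H <- H + 3L * (u$alpha[i] == "CH3")
    O <- O + (u$beta[i] %in% c("ketone", "hydroxyl"))
  }
  out <- chem_formula(C = C, H = H, N = N, O = O)
  for (ev in backbone$tailoring) {
    if (ev$kind == "hydroxylation") {
      out <- formula_add(out, c(O = 1L))
    }
  }
  if (backbone$amine_protected) {
    pg <- chem$protecting_groups[[chem$default_protecting_group]]
    out <- formula_add(out, pg)
  }
  out
}

#' Graph-side degrees of unsaturation of a cyclized backbone
#'
#' Counts rings and pi bonds directly on the backbone graph (macrolactam
#' ring + amide carbonyl + ketones + enoyl double bonds + the protecting
#' amide while present). Must equal [dbe()] of [molecular_formula()] for
#' every consistent backbone.
#'
#' @param backbone A cyclized `pks_backbone`.
#' @return Integer DBE.
#' @export
backbone_dbe <- function(backbone) {
  stopifnot(inherits(backbone, "pks_backbone"),
            !is.null(backbone$ring_size))
  1L + 1L + sum(backbone$units$beta == "ketone") +
    sum(backbone$units$beta == "enoyl") +
    as.integer(backbone$amine_protected)
}

# ---- masses ---------------------------------------------------------------

#' Unrounded monoisotopic mass of a formula
#'
#' @param formula A `chem_formula` (or named count vector).
#' @param chem Chemistry configuration (element mass table).
#' @return Mass in Da, full precision.
#' @export
monoisotopic_mass <- function(formula, chem = load_chem_config()) {
  if (length(formula) == 0L) return(0)
  els <- names(formula)
  unknown <- setdiff(els, names(chem$element_masses))
  if (length(unknown)) stop("unknown element symbol: ",
                            paste(unknown, collapse = ", "))
  sum(unlist(formula) * unlist(chem$element_masses[els]))
}

#' Adduct m/z of a formula
#'
#' Reported following the standard "calcd" tabulation convention: the
#' neutral monoisotopic mass and the neutral adduct atom mass are each
#' rounded half-even to 4 decimals, then summed (electron mass
#' neglected). Internal arithmetic is full precision; rounding happens
#' only at this reporting boundary.
#'
#' @param formula A `chem_formula`; may be empty for an adduct-only
#'   query.
#' @param adduct One of the configured adducts (`"[M+H]+"`, `"[M+Na]+"`,
#'   `"M"`).
#' @param chem Chemistry configuration.
#' @return m/z in Da at 4 decimal places.
#' @export
#' @examples
#' monoisotopic_mz(chem_formula(C = 28, H = 35, N = 1, O = 6), "[M+H]+")
monoisotopic_mz <- function(formula, adduct = "[M+H]+",
                            chem = load_chem_config()) {
  add <- chem$adducts[[adduct]]
  if (is.null(add)) stop("unknown adduct: ", adduct, " (configured: ",
                         paste(names(chem$adducts), collapse = ", "), ")")
  round(monoisotopic_mass(formula, chem), 4) +
    round(monoisotopic_mass(add, chem), 4)
}

#' @export
print.pks_backbone <- function(x, ...) {
  cat(sprintf("<pks_backbone> starter %s + %d extension unit(s)%s\n",
              x$starter$name, nrow(x$units),
              if (!is.null(x$ring_size))
                sprintf(", %d-membered macrolactam", x$ring_size)
              else " (uncyclized)"))
  print.data.frame(x$units)
  if (length(x$tailoring)) {
    cat("  tailoring:", paste(vapply(x$tailoring, function(e)
      sprintf("%s@%s", e$kind, e$site), ""), collapse = ", "), "\n")
  }
  invisible(x)
}
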