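# Locate PKS catalytic domains in protein sequences and classify them by
# sequence signatures: AT substrate choice (malonyl vs methylmalonyl via
# the specificity window downstream of the GHSxG serine), KR A/B typing
# and the implied beta-hydroxyl configuration, and per-domain catalytic
# activity checks. Scanning is anchored-regex based over the configurable
# motif table, not profile-HMM: intended for annotation-validated real
# input and for synthetic fixtures with embedded motifs.

DOMAIN_CLASSES <- c("KS", "AT", "DH", "ER", "KR", "ACP", "TE")

# All matches of a POSIX regex in a string; X never matches anything.
regex_hits <- function(seq, pattern) {
  m <- gregexpr(pattern, seq)[[1]]
  if (m[1] == -1L) return(data.frame(pos = integer(), len = integer()))
  data.frame(pos = as.integer(m), len = attr(m, "match.length"))
}

empty_hits <- function() {
  data.frame(domain_class = character(), start_aa = integer(),
             end_aa = integer(), anchor_motif = character(),
             anchor_pos = integer(), source = character(),
             stringsAsFactors = FALSE)
}

#' Scan a protein for PKS catalytic domains
#'
#' If `annotations` are supplied they are validated against the sequence
#' and passed through (`source = "annotation"`). Otherwise every domain
#' class in the signature table is located by its anchor motif; a domain
#' window of `width_up`/`width_down` residues is drawn around each anchor,
#' clamped to the sequence. Hits are ordered by start; overlapping later
#' hits of the same class are discarded (earlier anchor wins) and windows
#' of different classes are trimmed so hits never overlap.
#'
#' @param protein_seq Amino-acid string, length >= 50.
#' @param annotations Optional pre-annotated hits: data frame with columns
#'   `domain_class`, `start_aa`, `end_aa` (1-based inclusive).
#' @param config Signature configuration, see [load_signature_config()].
#' @return A `domain_hits` data frame: `domain_class`, `start_aa`,
#'   `end_aa`, `anchor_motif`, `anchor_pos`, `source`. Zero rows when
#'   nothing matches.
#' @export
scan_domains <- function(protein_seq, annotations = NULL,
                         config = load_signature_config()) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  protein_seq <- toupper(gsub("*", "", protein_seq, fixed = TRUE))
  n <- nchar(protein_seq)
  if (n < 50) stop("protein sequence shorter than 50 residues")

  if (!is.null(annotations)) {
    need <- c("domain_class", "start_aa", "end_aa")
    stopifnot(all(need %in% names(annotations)))
    if (nrow(annotations) &&
        (min(annotations$start_aa) < 1 || max(annotations$end_aa) > n)) {
      stop("annotation coordinates outside the sequence")
    }
    stopifnot(all(annotations$domain_class %in% DOMAIN_CLASSES),
              all(annotations$start_aa <= annotations$end_aa))
    out <- data.frame(
      domain_class = annotations$domain_class,
      start_aa = as.integer(annotations$start_aa),
      end_aa = as.integer(annotations$end_aa),
      anchor_motif = if ("anchor_motif" %in% names(annotations))
        annotations$anchor_motif else
        substr(rep(protein_seq, nrow(annotations)),
               annotations$start_aa, annotations$end_aa),
      anchor_pos = if ("anchor_pos" %in% names(annotations))
        as.integer(annotations$anchor_pos) else
        as.integer(annotations$start_aa),
      source = "annotation", stringsAsFactors = FALSE)
    out <- out[order(out$start_aa), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("domain_hits", "data.frame")
    return(out)
  }

  hits <- empty_hits()
  for (cls in names(config$domains)) {
    dc <- config$domains[[cls]]
    found <- regex_hits(protein_seq, dc$anchor)
    for (i in seq_len(nrow(found))) {
      a <- found$pos[i]
      hits <- rbind(hits, data.frame(
        domain_class = cls,
        start_aa = max(1L, a - as.integer(dc$width_up)),
        end_aa = min(n, a + as.integer(dc$width_down)),
        anchor_motif = substr(protein_seq, a, a + found$len[i] - 1L),
        anchor_pos = a, source = "motif_scan", stringsAsFactors = FALSE))
    }
  }
  if (nrow(hits) == 0L) {
    class(hits) <- c("domain_hits", "data.frame")
    return(hits)
  }
  hits <- hits[order(hits$anchor_pos, hits$domain_class), , drop = FALSE]
  # same-class overlap: keep the earlier anchor
  keep <- rep(TRUE, nrow(hits))
  last_end <- list()
  for (i in seq_len(nrow(hits))) {
    cls <- hits$domain_class[i]
    le <- last_end[[cls]]
    if (!is.null(le) && hits$start_aa[i] <= le) {
      keep[i] <- FALSE
    } else {
      last_end[[cls]] <- hits$end_aa[i]
    }
  }
  hits <- hits[keep, , drop = FALSE]
  # cross-class overlap: trim neighbouring windows at the midpoint between
  # anchors so every hit still contains its anchor motif
  if (nrow(hits) > 1L) {
    for (i in seq_len(nrow(hits) - 1L)) {
      if (hits$end_aa[i] >= hits$start_aa[i + 1L]) {
        cut <- (hits$anchor_pos[i] + hits$anchor_pos[i + 1L]) %/% 2L
        hits$end_aa[i] <- min(hits$end_aa[i], cut)
        hits$start_aa[i + 1L] <- max(hits$start_aa[i + 1L], cut + 1L)
      }
    }
  }
  rownames(hits) <- NULL
  class(hits) <- c("domain_hits", "data.frame")
  hits
}

#' Classify AT substrate specificity
#'
#' Locates the GHSxG acyltransferase active-site motif and compares the
#' specificity window at a configurable offset downstream against the
#' reference patterns (default: YASH = methylmalonyl, HAFH = malonyl).
#' Anything else is `unknown` (calls are total and single-valued).
#'
#' @param at_region Amino-acid string covering the AT domain.
#' @param config Signature configuration.
#' @return An `at_call`: list with `substrate`
#'   (`malonyl`/`methylmalonyl`/`unknown`), `signature_window`, `evidence`.
#' @export
classify_at_substrate <- function(at_region,
                                  config = load_signature_config()) {
  at_region <- toupper(at_region)
  anchor <- regex_hits(at_region, config$domains$AT$anchor)
  mk <- function(substrate, window, evidence) {
    structure(list(substrate = substrate, signature_window = window,
                   evidence = evidence), class = "at_call")
  }
  if (nrow(anchor) == 0L) {
    return(mk("unknown", "", "no_active_site_motif"))
  }
  off <- as.integer(config$at$specificity_offset)
  wlen <- as.integer(config$at$window_length)
  wstart <- anchor$pos[1] + off
  if (wstart + wlen - 1L > nchar(at_region)) {
    return(mk("unknown", "", "window_out_of_range"))
  }
  window <- substr(at_region, wstart, wstart + wlen - 1L)
  for (substrate in names(config$at$patterns)) {
    if (identical(window, config$at$patterns[[substrate]])) {
      return(mk(substrate, window, sprintf("window_%s", substrate)))
    }
  }
  mk("unknown", window, "unmatched_window")
}

#' @export
print.at_call <- function(x, ...) {
  cat(sprintf("<at_call> %s (window '%s', %s)\n",
              x$substrate, x$signature_window, x$evidence))
  invisible(x)
}

#' Classify KR type and beta-hydroxyl configuration
#'
#' B-type ketoreductases carry the conserved (L/V)D(D/N) motif in the
#' typing window and produce R-configured beta-hydroxyl groups; the
#' A-type tryptophan criterion (S-configured product) is an extrapolated
#' rule from the KR-typing literature and is flagged as such in the
#' evidence field. A KR whose catalytic tyrosine rule fails is called
#' `inactive`. All inputs yield a call.
#'
#' @param kr_region Amino-acid string covering the KR domain.
#' @param config Signature configuration.
#' @return A `kr_call`: list with `kr_type` (`A`/`B`/`inactive`/
#'   `unknown`), `motif` (matched string or `""`), `beta_oh_config`
#'   (`R`/`S`/`none`) and `evidence`.
#' @export
classify_kr_type <- function(kr_region, config = load_signature_config()) {
  kr_region <- toupper(kr_region)
  mk <- function(type, motif, conf, evidence) {
    structure(list(kr_type = type, motif = motif, beta_oh_config = conf,
                   evidence = evidence), class = "kr_call")
  }
  kc <- config$kr
  anchor <- regex_hits(kr_region, config$domains$KR$anchor)
  wstart <- if (nrow(anchor)) anchor$pos[1] + as.integer(kc$window_offset)
            else 1L
  wend <- min(nchar(kr_region), wstart + as.integer(kc$window_length) - 1L)
  window <- substr(kr_region, wstart, wend)
  # catalytic tyrosine rule first: no active site, no stereochemistry
  cat_rules <- config$domains$KR$catalytic
  for (rule in cat_rules) {
    if (!is.null(rule$pattern) &&
        nrow(regex_hits(kr_region, rule$pattern)) == 0L) {
      return(mk("inactive", "", "none",
                sprintf("missing_%s", rule$name)))
    }
  }
  bm <- regex_hits(window, kc$b_motif)
  if (nrow(bm)) {
    motif <- substr(window, bm$pos[1], bm$pos[1] + bm$len[1] - 1L)
    return(mk("B", motif, "R", "b_motif"))
  }
  if (grepl(kc$a_residue, window, fixed = TRUE)) {
    return(mk("A", kc$a_residue, "S", "a_residue_extrapolated"))
  }
  mk("unknown", "", "none", "no_typing_motif")
}

#' @export
print.kr_call <- function(x, ...) {
  cat(sprintf("<kr_call> type %s, beta-OH %s (%s)\n",
              x$kr_type, x$beta_oh_config, x$evidence))
  invisible(x)
}

#' Check the catalytic activity of a domain hit
#'
#' Evaluates the per-class essential-residue rules (KS active-site
#' cysteine, AT serine of GHSxG, DH histidine of the HxxxGxxxxP motif, KR
#' catalytic tyrosine, ACP/TE serine of the phosphopantetheine /
#' thioesterase motif). A domain is active iff no rule fails.
#'
#' @param hit One row of a `domain_hits` data frame (or a list with
#'   `domain_class`, `start_aa`, `end_aa`, `anchor_pos`).
#' @param protein_seq The protein the hit was found in.
#' @param config Signature configuration.
#' @return An `activity_call`: list with `domain_class`, `active`
#'   (logical) and `missing_residues` (character vector of failed rules).
#' @export
check_catalytic_activity <- function(hit, protein_seq,
                                     config = load_signature_config()) {
  cls <- as.character(hit$domain_class)
  if (!cls %in% names(config$domains)) {
    stop("unknown domain class: ", cls)
  }
  protein_seq <- toupper(protein_seq)
  region <- substr(protein_seq, hit$start_aa, hit$end_aa)
  anchor <- as.integer(hit$anchor_pos)
  missing <- character()
  for (rule in config$domains[[cls]]$catalytic) {
    ok <- if (!is.null(rule$pattern)) {
      nrow(regex_hits(region, rule$pattern)) > 0L
    } else {
      substr(protein_seq, anchor + rule$offset, anchor + rule$offset) ==
        rule$residue
    }
    if (!ok) missing <- c(missing, rule$name)
  }
  structure(list(domain_class = cls, active = length(missing) == 0L,
                 missing_residues = missing),
            class = "activity_call")
}

#' @export
print.activity_call <- function(x, ...) {
  cat(sprintf("<activity_call> %s: %s%s\n", x$domain_class,
              if (x$active) "active" else "inactive",
              if (length(x$missing_residues))
                paste0(" (missing ",
                       paste(x$missing_residues, collapse = ", "), ")")
              else ""))
  invisible(x)
}
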