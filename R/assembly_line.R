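# Group domain hits into modules, order modules across genes by
# chromosomal position (the collinearity rule), and evaluate
# docking-domain linkage between consecutive proteins.

#' Group domain hits into PKS modules
#'
#' A new module opens at each KS hit; domains up to (not including) the
#' next KS belong to it. A leading ACP (with any flanking non-KS domains)
#' before the first KS of the first gene forms the loading module (index
#' 0). Modules are numbered consecutively in gene order. A KS-opened
#' module lacking an AT is recorded with `at_call = NULL` and a
#' "malformed module" warning.
#'
#' @param genes A [pks_genes] data frame (rows in chromosomal order).
#' @param hits_by_gene Named list of `domain_hits` data frames, one per
#'   `gene_id`; computed with [scan_domains()] when omitted.
#' @param config Signature configuration.
#' @return A `pks_modules` list; each element has `module_index`,
#'   `gene_id`, `domains` (ordered `domain_hits`), `at_call`, `kr_call`,
#'   `activity` (list of `activity_call` per domain), `is_loading`.
#' @export
build_modules <- function(genes, hits_by_gene = NULL,
                          config = load_signature_config()) {
  stopifnot(inherits(genes, "pks_genes"))
  if (is.null(hits_by_gene)) {
    hits_by_gene <- lapply(seq_len(nrow(genes)), function(i)
      scan_domains(genes$protein[i], config = config))
    names(hits_by_gene) <- genes$gene_id
  }
  modules <- list()
  idx <- 0L
  for (gi in seq_len(nrow(genes))) {
    gid <- genes$gene_id[gi]
    seq <- genes$protein[gi]
    hits <- hits_by_gene[[gid]]
    if (is.null(hits) || nrow(hits) == 0L) next
    stopifnot(!is.unsorted(hits$start_aa))
    ks_at <- which(hits$domain_class == "KS")
    # leading non-KS domains on the first module-bearing gene: loading
    lead_end <- if (length(ks_at)) ks_at[1] - 1L else nrow(hits)
    if (lead_end > 0L && length(modules) == 0L && idx == 0L) {
      lead <- hits[seq_len(lead_end), , drop = FALSE]
      if ("ACP" %in% lead$domain_class) {
        modules[[length(modules) + 1L]] <-
          new_module(0L, gid, lead, seq, config, is_loading = TRUE)
      }
    }
    for (k in seq_along(ks_at)) {
      from <- ks_at[k]
      to <- if (k < length(ks_at)) ks_at[k + 1L] - 1L else nrow(hits)
      idx <- idx + 1L
      modules[[length(modules) + 1L]] <-
        new_module(idx, gid, hits[from:to, , drop = FALSE], seq, config,
                   is_loading = FALSE)
    }
  }
  structure(modules, class = "pks_modules")
}

new_module <- function(index, gene_id, domains, protein_seq, config,
                       is_loading) {
  rownames(domains) <- NULL
  classes <- domains$domain_class
  at_call <- NULL
  kr_call <- NULL
  if (!is_loading) {
    if (!"AT" %in% classes) {
      warning(sprintf("malformed module %d in %s: no AT domain",
                      index, gene_id))
    } else {
      at_row <- domains[match("AT", classes), ]
      at_call <- classify_at_substrate(
        substr(protein_seq, at_row$start_aa, at_row$end_aa), config)
    }
    if ("KR" %in% classes) {
      kr_row <- domains[match("KR", classes), ]
      kr_call <- classify_kr_type(
        substr(protein_seq, kr_row$start_aa, kr_row$end_aa), config)
    }
  }
  activity <- lapply(seq_len(nrow(domains)), function(i)
    check_catalytic_activity(domains[i, ], protein_seq, config))
  names(activity) <- make.unique(classes)
  structure(list(module_index = index, gene_id = gene_id,
                 domains = domains, at_call = at_call, kr_call = kr_call,
                 activity = activity, is_loading = is_loading),
            class = "pks_module")
}

#' @export
print.pks_module <- function(x, ...) {
  cat(sprintf("<pks_module> %s module %d [%s]: %s\n",
              x$gene_id, x$module_index,
              if (x$is_loading) "loading" else "extension",
              paste(x$domains$domain_class, collapse = "-")))
  invisible(x)
}

#' @export
print.pks_modules <- function(x, ...) {
  cat(sprintf("<pks_modules> %d module(s)\n", length(x)))
  for (m in x) print(m)
  invisible(x)
}

# ---- docking domains ------------------------------------------------------

# Max-over-windows heptad periodicity score of a terminal segment: for
# each window and register frame, min(fraction of a/d positions that are
# hydrophobic, fraction of remaining positions that are polar).
heptad_score <- function(seq, config) {
  dk <- config$docking
  n <- nchar(seq)
  w <- as.integer(dk$min_len)
  if (n < w) return(0)
  chars <- strsplit(seq, "")[[1]]
  hyd <- chars %in% strsplit(dk$hydrophobic, "")[[1]]
  pol <- chars %in% strsplit(dk$polar, "")[[1]]
  best <- 0
  for (s in 1:(n - w + 1L)) {
    i <- s:(s + w - 1L)
    for (f in 0:6) {
      ad <- ((i - s + f) %% 7L) %in% c(0L, 3L)
      sc <- min(mean(hyd[i][ad]), mean(pol[i][!ad]))
      if (sc > best) best <- sc
    }
  }
  best
}

#' Detect docking domains at protein termini
#'
#' The terminal regions outside the first/last domain hit are scored with
#' a sliding-window heptad-periodicity heuristic (a stand-in for
#' structural prediction of the coiled-coil docking fold); a terminus
#' qualifies when it is at least `docking$min_len` residues long and its
#' best window reaches `docking$score_threshold`. A dock class is
#' assigned when one of the configured class tags occurs in the region,
#' else `"unclassified"`.
#'
#' @param protein_seq Amino-acid string.
#' @param hits `domain_hits` for the protein (from [scan_domains()]).
#' @param config Signature configuration.
#' @return List with elements `N` and `C`, each a `docking_end`: list
#'   with `terminus`, `present`, `dock_class` (`NULL` when absent),
#'   `score`, `length`.
#' @export
detect_docking <- function(protein_seq, hits,
                           config = load_signature_config()) {
  protein_seq <- toupper(protein_seq)
  n <- nchar(protein_seq)
  nreg <- if (nrow(hits)) substr(protein_seq, 1L, min(hits$start_aa) - 1L)
          else protein_seq
  creg <- if (nrow(hits)) substr(protein_seq, max(hits$end_aa) + 1L, n)
          else ""
  one <- function(region, terminus) {
    score <- heptad_score(region, config)
    present <- nchar(region) >= as.integer(config$docking$min_len) &&
      score >= config$docking$score_threshold
    dock_class <- NULL
    if (present) {
      dock_class <- "unclassified"
      for (cls in names(config$docking$class_tags)) {
        if (grepl(config$docking$class_tags[[cls]], region, fixed = TRUE)) {
          dock_class <- cls
          break
        }
      }
    }
    structure(list(terminus = terminus, present = present,
                   dock_class = dock_class, score = score,
                   length = nchar(region)),
              class = "docking_end")
  }
  list(N = one(nreg, "N"), C = one(creg, "C"))
}

#' @export
print.docking_end <- function(x, ...) {
  cat(sprintf("<docking_end> %s-terminus: %s%s (score %.2f over %d aa)\n",
              x$terminus, if (x$present) "present" else "absent",
              if (x$present) paste0(", class ", x$dock_class) else "",
              x$score, x$length))
  invisible(x)
}

docking_compatible <- function(c_end, n_end, config) {
  if (!isTRUE(c_end$present) || !isTRUE(n_end$present)) return(FALSE)
  pairs <- config$docking$pairing
  if (is.null(pairs) || length(pairs) == 0L) return(TRUE)
  if (identical(c_end$dock_class, "unclassified") ||
      identical(n_end$dock_class, "unclassified")) {
    return(TRUE)  # presence-only evidence; no class contradiction
  }
  any(vapply(pairs, function(p)
    identical(p[[1]], c_end$dock_class) &&
      identical(p[[2]], n_end$dock_class), logical(1)))
}

# ---- assembly line --------------------------------------------------------

#' Order modules into a collinear assembly line
#'
#' Genes are sorted by genomic start coordinate (reversed when the
#' cluster is minus-strand), modules renumbered globally in that order,
#' and docking compatibility evaluated pairwise between consecutive
#' proteins. Order relies on genomic coordinates only; mixed strands
#' among the PKS genes are an error unless an explicit gene order is
#' supplied.
#'
#' @param genes A [pks_genes] data frame of the module-bearing genes.
#' @param hits_by_gene Optional named list of `domain_hits` per gene.
#' @param config Signature configuration.
#' @param order_override Optional character vector of gene ids giving the
#'   subunit order explicitly (required for mixed-strand input).
#' @return An `assembly_line`: list with `modules` (a `pks_modules`
#'   list), `gene_order`, `docking_links` (data frame: upstream,
#'   downstream, compatible), `te_present`, `loading_present`.
#' @export
order_assembly_line <- function(genes, hits_by_gene = NULL,
                                config = load_signature_config(),
                                order_override = NULL) {
  stopifnot(inherits(genes, "pks_genes"))
  if (is.null(order_override)) {
    strands <- unique(genes$strand)
    if (length(strands) > 1L) {
      stop("PKS genes on mixed strands; supply order_override ",
           "with the explicit gene order")
    }
    ord <- order(genes$start, genes$gene_id)
    if (identical(strands, "-")) ord <- rev(ord)
    gene_order <- genes$gene_id[ord]
  } else {
    stopifnot(all(order_override %in% genes$gene_id),
              length(order_override) == nrow(genes))
    gene_order <- order_override
  }
  genes <- genes[match(gene_order, genes$gene_id), , drop = FALSE]
  class(genes) <- c("pks_genes", "data.frame")
  if (is.null(hits_by_gene)) {
    hits_by_gene <- lapply(seq_len(nrow(genes)), function(i)
      scan_domains(genes$protein[i], config = config))
    names(hits_by_gene) <- genes$gene_id
  }
  modules <- build_modules(genes, hits_by_gene, config)
  docks <- lapply(genes$gene_id, function(g)
    detect_docking(genes$protein[match(g, genes$gene_id)],
                   hits_by_gene[[g]], config))
  names(docks) <- genes$gene_id
  links <- data.frame(upstream = character(), downstream = character(),
                      compatible = logical(), stringsAsFactors = FALSE)
  if (nrow(genes) > 1L) {
    for (i in seq_len(nrow(genes) - 1L)) {
      up <- genes$gene_id[i]; dn <- genes$gene_id[i + 1L]
      links <- rbind(links, data.frame(
        upstream = up, downstream = dn,
        compatible = docking_compatible(docks[[up]]$C, docks[[dn]]$N,
                                        config),
        stringsAsFactors = FALSE))
    }
  }
  last_gene <- genes$gene_id[nrow(genes)]
  te_present <- any(vapply(modules, function(m)
    m$gene_id == last_gene && "TE" %in% m$domains$domain_class,
    logical(1)))
  structure(list(modules = modules, gene_order = gene_order,
                 docking = docks, docking_links = links,
                 te_present = te_present,
                 loading_present = any(vapply(modules, `[[`, TRUE,
                                              "is_loading"))),
            class = "assembly_line")
}

#' Extension modules of an assembly line
#'
#' @param line An `assembly_line`.
#' @return The `pks_modules` list without the loading module.
#' @export
extension_modules <- function(line) {
  stopifnot(inherits(line, "assembly_line"))
  structure(Filter(function(m) !m$is_loading, line$modules),
            class = "pks_modules")
}

#' @export
print.assembly_line <- function(x, ...) {
  ext <- extension_modules(x)
  cat(sprintf(
    "<assembly_line> %d protein(s), %d extension module(s)%s%s\n",
    length(x$gene_order), length(ext),
    if (x$loading_present) " + loading" else "",
    if (x$te_present) " + TE" else ""))
  cat("  gene order:", paste(x$gene_order, collapse = " -> "), "\n")
  for (m in x$modules) {
    at <- if (!is.null(m$at_call)) m$at_call$substrate else "-"
    kr <- if (!is.null(m$kr_call)) m$kr_call$kr_type else "-"
    cat(sprintf("  [%2d] %-6s %-22s AT:%-13s KR:%s\n", m$module_index,
                m$gene_id, paste(m$domains$domain_class, collapse = "-"),
                at, kr))
  }
  if (nrow(x$docking_links)) {
    ok <- sum(x$docking_links$compatible)
    cat(sprintf("  docking links: %d/%d compatible\n", ok,
                nrow(x$docking_links)))
  }
  invisible(x)
}

#' @export
summary.assembly_line <- function(object, ...) {
  ext <- extension_modules(object)
  at <- vapply(ext, function(m)
    if (is.null(m$at_call)) "missing" else m$at_call$substrate, "")
  kr <- vapply(ext, function(m)
    if (is.null(m$kr_call)) "none" else m$kr_call$kr_type, "")
  list(n_genes = length(object$gene_order),
       n_extension_modules = length(ext),
       loading_present = object$loading_present,
       te_present = object$te_present,
       at_substrates = table(at), kr_types = table(kr),
       docking_compatible = sum(object$docking_links$compatible),
       docking_links = nrow(object$docking_links))
}
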