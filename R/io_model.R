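# Core domain types and readers/writers shared by all pipeline stages.
#
# Gene sets are plain data frames (class "pks_genes") with one row per CDS:
# gene_id, start, end (1-based inclusive genomic bp), strand ("+"/"-"),
# role (free-text functional annotation) and protein (amino-acid string).
# Coordinates follow the GenBank convention throughout: 1-based, inclusive
# on both ends, spans computed as end - start + 1.

#' Construct a gene set
#'
#' @param gene_id Character vector of unique gene labels.
#' @param protein Amino-acid sequences (uppercased; `*` stops stripped;
#'   `X` permitted and never matched by any signature).
#' @param start,end 1-based inclusive genomic coordinates.
#' @param strand `"+"` or `"-"`.
#' @param role Free-text functional annotation (e.g. "Polyketide
#'   synthase", "MFS transporter").
#' @return A `pks_genes` data frame ordered by ascending start coordinate
#'   (ties broken by `gene_id`).
#' @export
pks_genes <- function(gene_id, protein, start, end,
                      strand = "+", role = "") {
  n <- length(gene_id)
  stopifnot(length(protein) == n, length(start) == n, length(end) == n)
  strand <- rep_len(strand, n)
  role <- rep_len(role, n)
  if (anyDuplicated(gene_id)) {
    stop("gene_id values must be unique within a cluster")
  }
  protein <- toupper(gsub("*", "", protein, fixed = TRUE))
  if (any(nchar(protein) == 0L)) {
    stop("protein sequences must be non-empty for CDS records")
  }
  bad <- grepl("[^A-Z]", protein)
  if (any(bad)) stop("non-letter characters in protein sequence: ",
                     paste(gene_id[bad], collapse = ", "))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("start must be <= end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(gene_id = as.character(gene_id), protein = protein,
                   start = start, end = end, strand = strand,
                   role = as.character(role), stringsAsFactors = FALSE)
  df <- df[order(df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pks_genes", "data.frame")
  df
}

#' @export
print.pks_genes <- function(x, ...) {
  cat(sprintf("<pks_genes> %d CDS record(s)\n", nrow(x)))
  show <- x
  show$protein <- paste0(substr(show$protein, 1, 12), "... [",
                         nchar(x$protein), " aa]")
  print.data.frame(show, ...)
  invisible(x)
}

# ---- GenBank flat file ----------------------------------------------------

# Parse a GenBank location string: handles complement(), join(), order(),
# and partial-end markers (< >). Returns list(start, end, strand).
parse_gb_location <- function(loc) {
  strand <- "+"
  txt <- gsub("[<>[:space:]]", "", loc)
  if (grepl("^complement\\(", txt)) {
    strand <- "-"
    txt <- sub("^complement\\((.*)\\)$", "\\1", txt)
  }
  txt <- sub("^(join|order)\\((.*)\\)$", "\\2", txt)
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  bounds <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", p))[[1]]
    if (length(m) == 0L) stop("unparseable GenBank location: ", loc)
    a <- as.numeric(m[2])
    b <- if (nzchar(m[4])) as.numeric(m[4]) else a
    c(a, b)
  })
  rng <- range(unlist(bounds))
  list(start = rng[1], end = rng[2], strand = strand)
}

#' Read CDS features from a GenBank flat file
#'
#' Parses the FEATURES table of a GenBank flat file (the format of
#' annotated BGC records such as accession KX230849) and returns one gene
#' record per CDS feature carrying a `/translation` qualifier. CDS without
#' a translation are skipped with a warning. Minus-strand and
#' `join(...)`-location features are normalised to their leftmost/rightmost
#' genomic coordinates.
#'
#' @param path Path to a GenBank flat file.
#' @return A [pks_genes] data frame ordered by ascending start coordinate.
#'   `gene_id` is taken from `/gene`, else `/locus_tag`, else `"CDS_<n>"`;
#'   `role` from `/product` when present.
#' @export
read_genbank_cluster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) {
    stop("not a GenBank flat file (no FEATURES block): ", path)
  }
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  feat <- lines[(fstart[1] + 1L):fend]

  # split the block into features: a new feature starts with a key at col 6
  is_key <- grepl("^ {5}\\S", feat)
  if (!any(is_key)) return(pks_genes(character(), character(),
                                     integer(), integer())[0, ])
  idx <- cumsum(is_key)
  keys <- sub("^ {5}(\\S+).*$", "\\1", feat[is_key])
  recs <- list(); n_cds <- 0L
  for (k in seq_len(max(idx))) {
    if (keys[k] != "CDS") next
    block <- feat[idx == k]
    lineno <- which(idx == k)[1] + fstart[1]
    n_cds <- n_cds + 1L
    # location = text after the key up to the first qualifier line
    qual_at <- grep("^ {21}/", block)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
    loc <- paste(trimws(sub("^ {5}CDS", "", block[1])),
                 paste(trimws(block[seq_len(loc_end)][-1]), collapse = ""),
                 sep = "")
    pos <- tryCatch(parse_gb_location(loc), error = function(e) {
      stop("unparseable CDS location near line ", lineno, ": ",
           conditionMessage(e))
    })
    quals <- parse_gb_qualifiers(block[seq_along(block) >= loc_end + 1L])
    if (is.null(quals$translation)) {
      warning("CDS near line ", lineno, " has no /translation; skipped")
      next
    }
    id <- quals$gene %||% quals$locus_tag %||% sprintf("CDS_%d", n_cds)
    recs[[length(recs) + 1L]] <- list(
      gene_id = id, protein = gsub("[[:space:]]", "", quals$translation),
      start = pos$start, end = pos$end, strand = pos$strand,
      role = quals$product %||% "")
  }
  if (length(recs) == 0L) {
    return(pks_genes(character(0), character(0), integer(0), integer(0)))
  }
  pks_genes(gene_id = vapply(recs, `[[`, "", "gene_id"),
            protein = vapply(recs, `[[`, "", "protein"),
            start = vapply(recs, `[[`, 0, "start"),
            end = vapply(recs, `[[`, 0, "end"),
            strand = vapply(recs, `[[`, "", "strand"),
            role = vapply(recs, `[[`, "", "role"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse qualifier lines ("/name=value", values possibly quoted and wrapped).
parse_gb_qualifiers <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "/")) {
      m <- regmatches(ln, regexec("^/([A-Za-z_]+)(=(.*))?$", ln))[[1]]
      cur <- m[2]
      val <- if (nzchar(m[3])) m[4] else "TRUE"
      out[[cur]] <- val
    } else if (!is.null(cur)) {
      out[[cur]] <- paste0(out[[cur]], ln)
    }
  }
  lapply(out, function(v) gsub("\"", "", v))
}

#' Write a gene set as a minimal GenBank flat file
#'
#' Emits a protein-annotation-only GenBank record (CDS features with
#' `/gene`, `/product` and `/translation` qualifiers; no nucleotide
#' sequence) sufficient to round-trip [read_genbank_cluster()] on
#' synthetic fixtures.
#'
#' @param genes A [pks_genes] data frame.
#' @param path Output file path.
#' @param locus Locus name written to the LOCUS line.
#' @return Invisibly, `path`.
#' @export
write_genbank_cluster <- function(genes, path, locus = "SYNTHETIC") {
  stopifnot(inherits(genes, "pks_genes"))
  glen <- if (nrow(genes)) max(genes$end) else 0L
  out <- c(sprintf("LOCUS       %s %d bp    DNA     linear   SYN", locus, glen),
           sprintf("DEFINITION  synthetic PKS cluster fixture (%d CDS).",
                   nrow(genes)),
           "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(genes))) {
    span <- sprintf("%d..%d", genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") span <- sprintf("complement(%s)", span)
    out <- c(out, sprintf("     CDS             %s", span),
             sprintf("                     /gene=\"%s\"", genes$gene_id[i]))
    if (nzchar(genes$role[i])) {
      out <- c(out, sprintf("                     /product=\"%s\"",
                            genes$role[i]))
    }
    tr <- genes$protein[i]
    chunks <- substring(tr, seq(1, nchar(tr), 44),
                        pmin(seq(1, nchar(tr), 44) + 43, nchar(tr)))
    out <- c(out,
             sprintf("                     /translation=\"%s", chunks[1]),
             if (length(chunks) > 1)
               sprintf("                     %s", chunks[-1]))
    out[length(out)] <- paste0(out[length(out)], "\"")
  }
  out <- c(out, "ORIGIN", "//")
  writeLines(out, path)
  invisible(path)
}

# ---- protein FASTA + gene-order table ------------------------------------

#' Read a protein FASTA plus gene-order table
#'
#' Alternative input route to GenBank: a protein FASTA (one record per
#' gene, names matching `gene_id`) together with a TSV gene table holding
#' the genomic metadata (columns `gene_id`, `start`, `end`, `strand`,
#' `role`).
#'
#' @param fasta_path Protein FASTA file.
#' @param table_path TSV gene table.
#' @return A [pks_genes] data frame.
#' @export
read_protein_cluster <- function(fasta_path, table_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  tab <- read.delim(table_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "strand", "role")
  if (!all(need %in% names(tab))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(aa))
  missing <- setdiff(tab$gene_id, ids)
  if (length(missing)) stop("gene table entries missing from FASTA: ",
                            paste(missing, collapse = ", "))
  seqs <- as.character(aa)[match(tab$gene_id, ids)]
  pks_genes(tab$gene_id, seqs, tab$start, tab$end, tab$strand, tab$role)
}

#' Write a gene set as protein FASTA plus gene-order table
#'
#' @param genes A [pks_genes] data frame.
#' @param fasta_path,table_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_protein_cluster <- function(genes, fasta_path, table_path) {
  stopifnot(inherits(genes, "pks_genes"))
  aa <- Biostrings::AAStringSet(genes$protein)
  names(aa) <- genes$gene_id
  Biostrings::writeXStringSet(aa, fasta_path)
  write.table(genes[, c("gene_id", "start", "end", "strand", "role")],
              table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, table_path))
}

# ---- cluster coordinate tables -------------------------------------------

#' Read an antiSMASH-style cluster coordinate table
#'
#' The TSV must carry a header `cluster<TAB>product<TAB>from<TAB>to` with
#' integer, 1-based inclusive coordinates (the shape of a BGC landscape
#' table). The genome length is an explicit input, never inferred from
#' the intervals.
#'
#' @param path TSV file path.
#' @param genome_length Genome length in bp (positive integer).
#' @return A `cluster_table` object: list with `intervals` (data frame in
#'   file order: cluster, product, from, to) and `genome_length`.
#' @export
#' @examples
#' tsv <- system.file("extdata", "sd85_bgc_table.tsv", package = "pksline")
#' ct <- read_cluster_table(tsv, genome_length = 8625724)
#' nrow(ct$intervals)
read_cluster_table <- function(path, genome_length) {
  stopifnot(is.numeric(genome_length), genome_length > 0)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("integer", "character",
                                   "character", "character"))
  need <- c("cluster", "product", "from", "to")
  if (!identical(names(tab), need)) {
    stop("cluster table must have header: ", paste(need, collapse = "\t"))
  }
  for (col in c("from", "to")) {
    bad <- grepl("[^0-9]", tab[[col]]) | !nzchar(tab[[col]])
    if (any(bad)) {
      stop(sprintf("non-integer coordinate in column '%s', row %d",
                   col, which(bad)[1]))
    }
    tab[[col]] <- as.integer(tab[[col]])
  }
  if (any(tab$from > tab$to)) {
    stop("from > to in cluster table row ", which(tab$from > tab$to)[1])
  }
  if (nrow(tab) && (min(tab$from) < 1 || max(tab$to) > genome_length)) {
    stop("interval outside [1, genome_length]")
  }
  cluster_table(tab, genome_length)
}

#' Construct a cluster table object
#'
#' @param intervals Data frame with columns cluster, product, from, to.
#' @param genome_length Genome length in bp.
#' @return A `cluster_table` object.
#' @export
cluster_table <- function(intervals, genome_length) {
  stopifnot(all(c("cluster", "product", "from", "to") %in% names(intervals)))
  intervals <- intervals[, c("cluster", "product", "from", "to"),
                         drop = FALSE]
  rownames(intervals) <- NULL
  if (nrow(intervals)) {
    stopifnot(all(intervals$from <= intervals$to),
              all(intervals$from >= 1),
              all(intervals$to <= genome_length))
  }
  structure(list(intervals = intervals,
                 genome_length = as.numeric(genome_length)),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d interval(s) on a %s bp genome\n",
              nrow(x$intervals), format(x$genome_length, big.mark = ",")))
  print(head(x$intervals, 8))
  if (nrow(x$intervals) > 8) cat("...\n")
  invisible(x)
}

#' Write a cluster table as TSV
#'
#' @param table A `cluster_table`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_cluster_table <- function(table, path) {
  stopifnot(inherits(table, "cluster_table"))
  write.table(table$intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- JSON stage reports ---------------------------------------------------

#' Construct a stage report
#'
#' All pipeline stages emit the same report envelope: a stage label, a
#' structured payload and a provenance block (input file names, a hash of
#' the active configuration, the seed in play).
#'
#' @param stage Stage label, e.g. `"audit"`.
#' @param payload Named list, JSON-serialisable.
#' @param inputs Character vector of input file names.
#' @param config Configuration list used (hashed into provenance).
#' @param seed Integer seed or `NULL`.
#' @return A `pks_report` object.
#' @export
new_report <- function(stage, payload = list(), inputs = character(),
                       config = list(), seed = NULL) {
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage),
            is.list(payload))
  if (length(payload) == 0L) {
    payload <- structure(list(), names = character())  # serialize as {}
  }
  structure(list(stage = stage, payload = payload,
                 provenance = list(inputs = as.character(inputs),
                                   config_hash = config_hash(config),
                                   seed = seed)),
            class = "pks_report")
}

#' Validate a report against the shipped schema
#'
#' Structural validation mirroring `inst/extdata/report-schema.json`:
#' required keys present with the right types.
#'
#' @param report A `pks_report` or an equivalent list.
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
validate_report <- function(report) {
  ok <- is.list(report) &&
    all(c("stage", "payload", "provenance") %in% names(report)) &&
    is.character(report$stage) && nzchar(report$stage) &&
    is.list(report$payload) &&
    is.list(report$provenance) &&
    all(c("inputs", "config_hash", "seed") %in% names(report$provenance))
  if (!ok) stop("report does not conform to the report schema")
  invisible(TRUE)
}

#' Write a stage report as JSON
#'
#' Serialisation is deterministic, so write/read/write round-trips are
#' byte-identical. Unserialisable payloads raise an error before any
#' output is written.
#'
#' @param report A `pks_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  txt <- tryCatch(
    jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                     digits = NA, null = "null"),
    error = function(e) stop("payload is not JSON-serialisable: ",
                             conditionMessage(e)))
  writeLines(txt, path)
  invisible(path)
}

#' Read a stage report back from JSON
#'
#' @param path JSON file path.
#' @return A `pks_report` object.
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  validate_report(obj)
  structure(obj, class = "pks_report")
}

#' @export
print.pks_report <- function(x, ...) {
  cat(sprintf("<pks_report> stage '%s' (config %s)\n",
              x$stage, x$provenance$config_hash))
  utils::str(x$payload, max.level = 2, give.attr = FALSE)
  invisible(x)
}
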