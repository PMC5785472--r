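# BGC landscape statistics from a cluster coordinate table: total
# occupied span (overlap-merged coverage), genome fraction, and counts
# by predicted product type.

#' BGC occupancy of a genome
#'
#' Intervals are merged where overlapping (coverage, so nothing is
#' double-counted) and spans summed with the inclusive convention
#' (to - from + 1). Megabases are reported to 2 decimals and the genome
#' fraction as a percentage to 1 decimal.
#'
#' @param table A `cluster_table` (see [read_cluster_table()]).
#' @return An `occupancy_summary`: list with `n_clusters`, `total_bp`,
#'   `total_mb`, `fraction_pct`, `genome_length`.
#' @export
#' @examples
#' tsv <- system.file("extdata", "sd85_bgc_table.tsv", package = "pksline")
#' occupancy(read_cluster_table(tsv, genome_length = 8625724))
occupancy <- function(table) {
  stopifnot(inherits(table, "cluster_table"))
  iv <- table$intervals
  if (nrow(iv) == 0L) stop("cluster table is empty")
  if (table$genome_length <= 0) stop("genome_length must be positive")
  if (min(iv$from) < 1 || max(iv$to) > table$genome_length) {
    stop("interval exceeds genome bounds")
  }
  merged <- IRanges::reduce(IRanges::IRanges(start = iv$from,
                                             end = iv$to))
  total_bp <- sum(IRanges::width(merged))
  structure(list(n_clusters = nrow(iv),
                 total_bp = total_bp,
                 total_mb = round(total_bp / 1e6, 2),
                 fraction_pct = round(100 * total_bp /
                                        table$genome_length, 1),
                 genome_length = table$genome_length),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf(
    "<occupancy_summary> %d clusters occupy %s bp (%.2f Mb), %.1f%% of the %s bp genome\n",
    x$n_clusters, format(x$total_bp, big.mark = ","), x$total_mb,
    x$fraction_pct, format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Count clusters by product-type group
#'
#' A cluster counts toward a group when any of the group's substrings
#' occurs (case-insensitively) in its product/type label; hybrid clusters
#' may count toward several groups. Matched cluster ids are returned for
#' auditability.
#'
#' @param table A `cluster_table`.
#' @param type_groups Named list mapping group name to a character vector
#'   of matching substrings; `NULL` loads the packaged default grouping.
#' @return A named list; each element has `count` and `cluster_ids`.
#' @export
count_by_type <- function(table, type_groups = NULL) {
  stopifnot(inherits(table, "cluster_table"))
  if (is.null(type_groups)) {
    type_groups <- yaml::read_yaml(
      system.file("extdata", "type_groups.yaml", package = "pksline"))$groups
  }
  if (length(type_groups) == 0L) stop("no type groups defined")
  iv <- table$intervals
  out <- lapply(names(type_groups), function(g) {
    pats <- type_groups[[g]]
    if (length(pats) == 0L) stop("empty group definition: ", g)
    hit <- rep(FALSE, nrow(iv))
    for (p in pats) {
      hit <- hit | grepl(p, iv$product, ignore.case = TRUE, fixed = FALSE)
    }
    list(count = sum(hit), cluster_ids = iv$cluster[hit])
  })
  names(out) <- names(type_groups)
  out
}
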