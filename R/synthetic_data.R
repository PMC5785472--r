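# Synthetic-fixture generator: multi-modular PKS proteins assembled from
# fixed domain scaffolds (neutral filler + anchor motifs + signature
# windows + docking termini) with a ground-truth record emitted
# alongside. Scaffolds are synthetic strings, not real sequences; the
# filler alphabet deliberately omits every residue that any anchor or
# signature rule requires, so motifs cannot arise by accident (and this
# is asserted at generation time). All randomness flows through the
# supplied seed; the global RNG state is left untouched.

FILLER_ALPHABET <- c("A", "E", "I", "K", "L", "M", "P", "Q", "R", "T",
                     "V", "F")
SCAFFOLD_LEN <- 160L
ANCHOR_AT <- 31L        # anchor offset within a scaffold (1-based)
GENE_GAP <- 8L          # filler between docking segment and scaffolds
DOCK_LEN <- 32L         # 4 heptads + class tag
KR_TYR_OFFSET <- 14L    # catalytic Y...N placed at anchor + 14
KR_MOTIF_OFFSET <- 29L  # typing motif placed at anchor + 29

filler <- function(n) {
  if (n <= 0L) return("")
  paste(sample(FILLER_ALPHABET, n, replace = TRUE), collapse = "")
}

# place insert strings at fixed 1-based offsets over a filler backdrop
with_inserts <- function(len, inserts) {
  chars <- strsplit(filler(len), "")[[1]]
  for (ins in inserts) {
    s <- strsplit(ins$seq, "")[[1]]
    chars[ins$pos:(ins$pos + length(s) - 1L)] <- s
  }
  paste(chars, collapse = "")
}

# domain scaffold: anchor motif (plus class-specific signature inserts)
domain_scaffold <- function(class, at_substrate = NULL, kr_type = NULL) {
  ins <- switch(class,
    KS = list(list(pos = ANCHOR_AT, seq = "DTACSSSLVA")),
    AT = list(list(pos = ANCHOR_AT, seq = "GHSQG"),
              list(pos = ANCHOR_AT + 30L,
                   seq = if (identical(at_substrate, "methylmalonyl"))
                     "YASH" else "HAFH")),
    DH = list(list(pos = ANCHOR_AT, seq = "HALLGQRSLP")),
    ER = list(list(pos = ANCHOR_AT, seq = "GGVGMAQ")),
    KR = c(list(list(pos = ANCHOR_AT, seq = "GGTGTLG"),
                list(pos = ANCHOR_AT + KR_TYR_OFFSET, seq = "YLLAN")),
           if (identical(kr_type, "B"))
             list(list(pos = ANCHOR_AT + KR_MOTIF_OFFSET, seq = "LDD"))
           else if (identical(kr_type, "A"))
             list(list(pos = ANCHOR_AT + KR_MOTIF_OFFSET, seq = "W"))),
    ACP = list(list(pos = ANCHOR_AT, seq = "GLDSL")),
    TE = list(list(pos = ANCHOR_AT, seq = "GWSMG")),
    stop("no scaffold for domain class ", class))
  with_inserts(SCAFFOLD_LEN, ins)
}

# 4-heptad coiled-coil-like docking segment plus a class tag
docking_segment <- function(dock_class, tags, terminus) {
  hyd <- c("L", "I", "V")
  pol <- c("E", "K", "Q", "A", "R")
  chars <- character(28L)
  for (p in seq_len(28L)) {
    chars[p] <- if (((p - 1L) %% 7L) %in% c(0L, 3L))
      sample(hyd, 1L) else sample(pol, 1L)
  }
  core <- paste(chars, collapse = "")
  tag <- tags[[dock_class]]
  if (terminus == "N") paste0(tag, core) else paste0(core, tag)
}

# generator-side unit rule, kept separate from the prediction code path
truth_unit <- function(at, reductive, kr_type) {
  alpha <- if (identical(at, "methylmalonyl")) "CH3" else "H"
  red <- sort(reductive)
  beta <- if (!"KR" %in% red) "ketone"
          else if (!"DH" %in% red) "hydroxyl"
          else if (!"ER" %in% red) "enoyl"
          else "methylene"
  stereo <- if (beta == "hydroxyl")
    switch(kr_type, B = "R", A = "S", "none") else "none"
  list(alpha = alpha, beta = beta, stereo = stereo,
       geometry = if (beta == "enoyl") "E" else "none")
}

random_module_spec <- function() {
  red <- sample(list(character(0), "KR", c("KR", "DH"),
                     c("KR", "DH", "ER")), 1L)[[1]]
  list(at = sample(c("malonyl", "methylmalonyl"), 1L,
                   prob = c(0.75, 0.25)),
       reductive = red,
       kr_type = if ("KR" %in% red)
         sample(c("B", "A"), 1L, prob = c(0.8, 0.2)) else NA_character_,
       te = FALSE)
}

validate_module_spec <- function(spec) {
  for (i in seq_along(spec)) {
    m <- spec[[i]]
    if (!is.null(m$kr_type) && !is.na(m$kr_type) &&
        !"KR" %in% m$reductive) {
      stop("module ", i, ": kr_type requested for a module without KR")
    }
    if ("KR" %in% m$reductive &&
        (is.null(m$kr_type) || is.na(m$kr_type))) {
      stop("module ", i, ": KR present but kr_type not given")
    }
    stopifnot(m$at %in% c("malonyl", "methylmalonyl"),
              all(m$reductive %in% c("KR", "DH", "ER")))
  }
  invisible(spec)
}

# domain class order of one extension module
module_classes <- function(m) {
  c("KS", "AT",
    intersect(c("DH", "ER", "KR"), m$reductive),
    "ACP", if (isTRUE(m$te)) "TE")
}

#' Generate a synthetic PKS assembly-line fixture
#'
#' Builds multi-modular PKS proteins by concatenating fixed domain
#' scaffolds carrying the canonical anchor motifs and signature windows
#' at known offsets, partitions the modules across genes, optionally
#' prepends a loading ACP and inserts docking-compatible termini at the
#' protein junctions, and emits the ground truth (architecture, anchor
#' coordinates, expected backbone units, docking classes) alongside.
#'
#' @param n_modules Number of extension modules (>= 1).
#' @param module_spec `"random"` or a list of per-module specs, each a
#'   list with `at` (`"malonyl"`/`"methylmalonyl"`), `reductive`
#'   (character subset of KR/DH/ER), `kr_type` (`"A"`/`"B"`, required
#'   with KR), `te` (logical, terminal module only).
#' @param seed Integer seed; identical seed and parameters reproduce
#'   byte-identical sequences and truth.
#' @param n_genes Number of proteins to spread the modules over
#'   (defaults to 1 + n_modules %/% 3, capped at n_modules).
#' @param gene_ids Optional gene names (defaults to pksA, pksB, ...).
#' @param loading Prepend a loading ACP to the first protein.
#' @param docking Insert docking segments at internal protein junctions.
#' @param te Append a TE to the final module (overrides the last module
#'   spec's `te`).
#' @param cluster_start Genomic coordinate of the first gene.
#' @return A `pks_fixture`: list with `genes` ([pks_genes]),
#'   `architecture` (per-gene module specs), `truth` (list: `modules`
#'   data frame, `units` data frame, `anchors` data frame, `docking`
#'   data frame), `seed`.
#' @export
generate_assembly_line <- function(n_modules, module_spec = "random",
                                   seed = 1L, n_genes = NULL,
                                   gene_ids = NULL, loading = TRUE,
                                   docking = TRUE, te = TRUE,
                                   cluster_start = 1000L) {
  stopifnot(n_modules >= 1L)
  withr::with_seed(seed, {
    spec <- if (identical(module_spec, "random")) {
      replicate(n_modules, random_module_spec(), simplify = FALSE)
    } else {
      stopifnot(length(module_spec) == n_modules)
      module_spec
    }
    if (te) spec[[n_modules]]$te <- TRUE
    validate_module_spec(spec)
    if (is.null(n_genes)) {
      n_genes <- min(n_modules, 1L + n_modules %/% 3L)
    }
    stopifnot(n_genes >= 1L, n_genes <= n_modules)
    if (is.null(gene_ids)) gene_ids <- paste0("pks", LETTERS[1:n_genes])
    stopifnot(length(gene_ids) == n_genes)
    # contiguous partition of modules over genes
    cuts <- sort(c(0L, sample(seq_len(n_modules - 1L),
                              n_genes - 1L), n_modules))
    per_gene <- lapply(seq_len(n_genes), function(g)
      (cuts[g] + 1L):cuts[g + 1L])
    build_fixture(spec, per_gene, gene_ids, loading, docking,
                  cluster_start, seed)
  })
}

# deterministic assembly given the drawn spec/partition (RNG already
# scoped by the caller; filler still consumes it)
build_fixture <- function(spec, per_gene, gene_ids, loading, docking,
                          cluster_start, seed) {
  n_genes <- length(per_gene)
  tag_names <- names(load_signature_config()$docking$class_tags)
  tags <- load_signature_config()$docking$class_tags
  anchors <- list(); units <- list(); mods <- list(); docks <- list()
  proteins <- character(n_genes)
  for (g in seq_len(n_genes)) {
    parts <- character(); pos <- 0L
    add <- function(s) {
      parts[length(parts) + 1L] <<- s
      pos <<- pos + nchar(s)
    }
    dock_n <- docking && g > 1L
    dock_c <- docking && g < n_genes
    class_n <- tag_names[(g - 2L) %% length(tag_names) + 1L]
    class_c <- tag_names[(g - 1L) %% length(tag_names) + 1L]
    if (dock_n) {
      add(docking_segment(class_n, tags, "N"))
      add(filler(GENE_GAP))
    }
    if (loading && g == 1L) {
      a <- pos + ANCHOR_AT
      add(domain_scaffold("ACP"))
      anchors[[length(anchors) + 1L]] <- data.frame(
        gene_id = gene_ids[g], module = 0L, domain_class = "ACP",
        anchor_pos = a, stringsAsFactors = FALSE)
    }
    for (m in per_gene[[g]]) {
      sp <- spec[[m]]
      for (cls in module_classes(sp)) {
        a <- pos + ANCHOR_AT
        add(domain_scaffold(cls, at_substrate = sp$at,
                            kr_type = sp$kr_type))
        anchors[[length(anchors) + 1L]] <- data.frame(
          gene_id = gene_ids[g], module = m, domain_class = cls,
          anchor_pos = a, stringsAsFactors = FALSE)
      }
      u <- truth_unit(sp$at, sp$reductive, sp$kr_type)
      units[[m]] <- data.frame(position = m, alpha = u$alpha,
                               beta = u$beta, stereo = u$stereo,
                               geometry = u$geometry,
                               stringsAsFactors = FALSE)
      mods[[m]] <- data.frame(
        module = m, gene_id = gene_ids[g], at = sp$at,
        reductive = paste(sort(sp$reductive), collapse = "+"),
        kr_type = sp$kr_type %||% NA_character_,
        te = isTRUE(sp$te), stringsAsFactors = FALSE)
    }
    if (dock_c) {
      add(filler(GENE_GAP))
      add(docking_segment(class_c, tags, "C"))
    }
    docks[[g]] <- data.frame(
      gene_id = gene_ids[g],
      n_present = dock_n, n_class = if (dock_n) class_n else NA,
      c_present = dock_c, c_class = if (dock_c) class_c else NA,
      stringsAsFactors = FALSE)
    proteins[g] <- paste(parts, collapse = "")
  }
  anchors <- do.call(rbind, anchors)
  assert_motif_safety(proteins, gene_ids, anchors)
  # genomic metadata: genes laid out left to right with 200 bp spacers
  starts <- integer(n_genes); ends <- integer(n_genes)
  at_bp <- as.integer(cluster_start)
  for (g in seq_len(n_genes)) {
    starts[g] <- at_bp
    ends[g] <- at_bp + 3L * (nchar(proteins[g]) + 1L) - 1L
    at_bp <- ends[g] + 200L
  }
  genes <- pks_genes(gene_ids, proteins, starts, ends, strand = "+",
                     role = "Polyketide synthase")
  structure(list(genes = genes,
                 architecture = list(spec = spec, per_gene = per_gene,
                                     gene_ids = gene_ids,
                                     loading = loading,
                                     docking = docking,
                                     cluster_start = cluster_start),
                 truth = list(modules = do.call(rbind, mods),
                              units = do.call(rbind, units),
                              anchors = anchors,
                              docking = do.call(rbind, docks)),
                 seed = seed),
            class = "pks_fixture")
}

# every anchor regex must occur exactly as often as the truth expects
assert_motif_safety <- function(proteins, gene_ids,
                                anchors, config = load_signature_config()) {
  for (g in seq_along(proteins)) {
    for (cls in names(config$domains)) {
      found <- regex_hits(proteins[g], config$domains[[cls]]$anchor)
      expected <- anchors$anchor_pos[anchors$gene_id == gene_ids[g] &
                                       anchors$domain_class == cls]
      if (!identical(as.integer(found$pos), as.integer(sort(expected)))) {
        stop("accidental or missing ", cls, " motif in generated gene ",
             gene_ids[g])
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.pks_fixture <- function(x, ...) {
  cat(sprintf(
    "<pks_fixture> %d gene(s), %d extension module(s), seed %d\n",
    nrow(x$genes), nrow(x$truth$units), x$seed))
  print(x$truth$modules)
  invisible(x)
}

#' Mutate a fixture with truth kept consistent
#'
#' Architecture-level mutations used to exercise the audit and search
#' stages: delete one module (the expected backbone loses that unit),
#' inject an orphan stand-alone trans-module gene into the genome
#' background, or ablate a single catalytic signature residue.
#'
#' @param fixture A `pks_fixture`.
#' @param op `"delete_module"`, `"inject_orphan_trans"` or
#'   `"ablate_residue"`.
#' @param k Module index for `delete_module`.
#' @param with_docking For `inject_orphan_trans`: give the orphan
#'   docking ends.
#' @param rule For `ablate_residue`: catalytic rule name (e.g.
#'   `"KS_cys"`, `"AT_ser"`, `"DH_his"`, `"KR_tyr"`, `"ACP_ser"`).
#' @param module For `ablate_residue`: extension module index to hit.
#' @return The mutated `pks_fixture`. Orphan genes accumulate in
#'   `fixture$genome_extra` (a [pks_genes] data frame).
#' @export
mutate_fixture <- function(fixture, op = c("delete_module",
                                           "inject_orphan_trans",
                                           "ablate_residue"),
                           k = NULL, with_docking = TRUE, rule = NULL,
                           module = NULL) {
  op <- match.arg(op)
  stopifnot(inherits(fixture, "pks_fixture"))
  arch <- fixture$architecture
  if (op == "delete_module") {
    n <- length(arch$spec)
    if (n <= 1L) stop("cannot delete the only module of a fixture")
    stopifnot(!is.null(k), k >= 1L, k <= n)
    spec <- arch$spec[-k]
    if (isTRUE(arch$spec[[n]]$te)) spec[[length(spec)]]$te <- TRUE
    per_gene <- lapply(arch$per_gene, function(mm) {
      mm <- setdiff(mm, k)
      mm - (mm > k)
    })
    keep <- lengths(per_gene) > 0L
    out <- withr::with_seed(fixture$seed,
      build_fixture(spec, per_gene[keep], arch$gene_ids[keep],
                    arch$loading, arch$docking, arch$cluster_start,
                    fixture$seed))
    out$genome_extra <- fixture$genome_extra
    return(out)
  }
  if (op == "inject_orphan_trans") {
    orphan <- withr::with_seed(fixture$seed + 7919L, {
      sp <- list(list(at = "malonyl", reductive = character(0),
                      kr_type = NA_character_, te = FALSE))
      fx <- build_fixture(sp, list(1L), "orphan1", loading = FALSE,
                          docking = FALSE, cluster_start = 900000L,
                          seed = fixture$seed + 7919L)
      g <- fx$genes
      if (with_docking) {
        tags <- load_signature_config()$docking$class_tags
        g$protein <- paste0(docking_segment(names(tags)[1], tags, "N"),
                            filler(GENE_GAP), g$protein,
                            filler(GENE_GAP),
                            docking_segment(names(tags)[2], tags, "C"))
      }
      g
    })
    extra <- fixture$genome_extra
    orphan$gene_id <- paste0("orphan", if (is.null(extra)) 1L else
      nrow(extra) + 1L)
    fixture$genome_extra <- if (is.null(extra)) orphan else {
      merged <- rbind(as.data.frame(extra), as.data.frame(orphan))
      class(merged) <- c("pks_genes", "data.frame")
      merged
    }
    return(fixture)
  }
  # ablate_residue
  stopifnot(!is.null(rule), !is.null(module))
  cls <- sub("_.*$", "", rule)
  an <- fixture$truth$anchors
  row <- an[an$module == module & an$domain_class == cls, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no unique ", cls, " domain in module ", module)
  }
  offset <- switch(rule, KS_cys = 3L, AT_ser = 2L, DH_his = 0L,
                   KR_tyr = KR_TYR_OFFSET, ACP_ser = 3L, TE_ser = 2L,
                   stop("unknown rule: ", rule))
  gi <- match(row$gene_id, fixture$genes$gene_id)
  p <- strsplit(fixture$genes$protein[gi], "")[[1]]
  p[row$anchor_pos + offset] <- "A"
  fixture$genes$protein[gi] <- paste(p, collapse = "")
  fixture$truth$ablated <- rbind(
    fixture$truth$ablated,
    data.frame(module = module, rule = rule, stringsAsFactors = FALSE))
  fixture
}

#' Background genome genes without PKS content
#'
#' Filler-only proteins (no anchor motifs, no docking termini), used as
#' the orphan-free genome background for trans-module searches.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return A [pks_genes] data frame.
#' @export
generate_genome_background <- function(n_genes = 20L, seed = 1L) {
  withr::with_seed(seed, {
    lens <- sample(200:800, n_genes, replace = TRUE)
    prots <- vapply(lens, filler, "")
    starts <- cumsum(c(2e6, lens[-n_genes] * 3 + 500))
    pks_genes(sprintf("bg%03d", seq_len(n_genes)), prots,
              starts, starts + lens * 3, strand = "+",
              role = "hypothetical protein")
  })
}

#' The synthetic sceliphrolactam assembly-line fixture
#'
#' A reconstruction of the sce cluster's PKS system as a synthetic
#' fixture: five proteins (sceN, sceO, sceQ, sceR, sceS) carrying a
#' loading ACP plus ten extension modules, methylmalonyl specificity
#' windows in modules 3 and 8, B-type KRs throughout, DH domains placed
#' for the polyene, a KR-only module in sceR, a TE on the final sceS
#' module, and docking termini at the four protein junctions. The
#' module-per-protein distribution is figure-derived (the source scheme
#' draws it rather than tabulating it), so this is a synthetic stand-in
#' for the deposited cluster sequence, not real sequence data.
#'
#' @param seed Integer seed for the filler residues.
#' @return A `pks_fixture`.
#' @export
sce_fixture <- function(seed = 85L) {
  mod <- function(at, red, kr = if ("KR" %in% red) "B" else NA_character_,
                  te = FALSE) {
    list(at = at, reductive = red, kr_type = kr, te = te)
  }
  spec <- list(
    mod("malonyl", c("KR", "DH")),        # 1 sceN
    mod("malonyl", character(0)),         # 2 sceN  (ketone)
    mod("methylmalonyl", c("KR", "DH")),  # 3 sceO  (C-27 methyl)
    mod("malonyl", c("KR", "DH")),        # 4 sceO
    mod("malonyl", c("KR", "DH")),        # 5 sceQ  (iterative candidate)
    mod("malonyl", "KR"),                 # 6 sceR  (C-11 hydroxyl)
    mod("malonyl", c("KR", "DH")),        # 7 sceS
    mod("methylmalonyl", c("KR", "DH")),  # 8 sceS  (C-26 methyl)
    mod("malonyl", c("KR", "DH")),        # 9 sceS
    mod("malonyl", c("KR", "DH"), te = TRUE))  # 10 sceS
  withr::with_seed(seed,
    build_fixture(spec,
                  per_gene = list(1:2, 3:4, 5L, 6L, 7:10),
                  gene_ids = c("sceN", "sceO", "sceQ", "sceR", "sceS"),
                  loading = TRUE, docking = TRUE,
                  cluster_start = 1237686L, seed = seed))
}

#' Generate a random cluster coordinate table with truth occupancy
#'
#' Intervals are drawn inside the genome bounds; with probability
#' `overlap_prob` an interval is shifted to overlap its predecessor.
#' Truth occupancy is computed with an exhaustive per-base coverage
#' vector (bit-vector), independently of [occupancy()].
#'
#' @param n_clusters Number of intervals (>= 0).
#' @param genome_length Genome length in bp.
#' @param overlap_prob Probability that an interval overlaps the
#'   previous one.
#' @param seed Integer seed.
#' @param len_range Interval length range.
#' @return List with `table` (a `cluster_table`) and `truth_bp` (covered
#'   bases by the bit-vector count).
#' @export
generate_cluster_table <- function(n_clusters, genome_length,
                                   overlap_prob = 0, seed = 1L,
                                   len_range = c(30L, 200L)) {
  stopifnot(n_clusters >= 0L)
  if (n_clusters > 0L && genome_length < 2L * max(len_range)) {
    stop("genome too small for the requested clusters")
  }
  withr::with_seed(seed, {
    iv <- data.frame(cluster = integer(), product = character(),
                     from = integer(), to = integer(),
                     stringsAsFactors = FALSE)
    types <- c("NRPS", "T1PKS", "Terpene", "Lantipeptide", "Unknown")
    prev_from <- NA_integer_; prev_to <- NA_integer_
    for (i in seq_len(n_clusters)) {
      len <- sample(len_range[1]:len_range[2], 1L)
      if (!is.na(prev_to) && runif(1) < overlap_prob) {
        from <- sample(prev_from:prev_to, 1L)
      } else {
        # overlap only by design: rejection-sample a clear placement
        for (try in 1:1000) {
          from <- sample.int(genome_length - len + 1L, 1L)
          clear <- nrow(iv) == 0L ||
            all(from + len - 1L < iv$from | from > iv$to)
          if (clear) break
          if (try == 1000L) stop("genome too small for the requested ",
                                 "clusters")
        }
      }
      to <- min(genome_length, from + len - 1L)
      iv <- rbind(iv, data.frame(cluster = i,
                                 product = sample(types, 1L),
                                 from = from, to = to,
                                 stringsAsFactors = FALSE))
      prev_from <- from; prev_to <- to
    }
    covered <- logical(genome_length)
    for (i in seq_len(nrow(iv))) covered[iv$from[i]:iv$to[i]] <- TRUE
    list(table = cluster_table(iv, genome_length),
         truth_bp = sum(covered))
  })
}

#' Write a fixture to disk
#'
#' Emits the protein FASTA, the gene-order TSV, a GenBank rendering and
#' the truth record as JSON, side by side.
#'
#' @param fixture A `pks_fixture`.
#' @param dir Output directory (created if needed).
#' @param basename File basename.
#' @return Invisibly, the named vector of paths written.
#' @export
write_fixture <- function(fixture, dir, basename = "fixture") {
  stopifnot(inherits(fixture, "pks_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(basename, ".faa")),
    table = file.path(dir, paste0(basename, "_genes.tsv")),
    genbank = file.path(dir, paste0(basename, ".gbk")),
    truth = file.path(dir, paste0(basename, "_truth.json")))
  write_protein_cluster(fixture$genes, paths[["fasta"]],
                        paths[["table"]])
  write_genbank_cluster(fixture$genes, paths[["genbank"]])
  writeLines(jsonlite::toJSON(fixture$truth, auto_unbox = TRUE,
                              pretty = TRUE, digits = NA),
             paths[["truth"]])
  invisible(paths)
}
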