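# Domain scanning and signature classification.

pad <- function(n) strrep("A", n)

test_that("a KS-AT-ACP construct yields three ordered hits", {
  fx <- generate_assembly_line(
    1, module_spec = list(list(at = "malonyl", reductive = character(0),
                               kr_type = NA_character_, te = FALSE)),
    seed = 2L, loading = FALSE, docking = FALSE, te = FALSE)
  hits <- scan_domains(fx$genes$protein[1])
  expect_equal(hits$domain_class, c("KS", "AT", "ACP"))
  expect_false(is.unsorted(hits$start_aa))
  # hits never overlap and each window contains its anchor motif
  expect_true(all(head(hits$end_aa, -1) < hits$start_aa[-1]))
  for (i in seq_len(nrow(hits))) {
    region <- substr(fx$genes$protein[1], hits$start_aa[i],
                     hits$end_aa[i])
    expect_true(grepl(hits$anchor_motif[i], region, fixed = TRUE))
  }
})

test_that("scanning recovers the generator truth exactly on every seed", {
  for (seed in 1:5) {
    fx <- generate_assembly_line(10, seed = seed)
    for (g in seq_len(nrow(fx$genes))) {
      gid <- fx$genes$gene_id[g]
      hits <- scan_domains(fx$genes$protein[g])
      truth <- fx$truth$anchors[fx$truth$anchors$gene_id == gid, ]
      truth <- truth[order(truth$anchor_pos), ]
      # precision and recall both 1: same classes at the same anchors
      expect_equal(hits$domain_class, truth$domain_class)
      expect_equal(hits$anchor_pos, truth$anchor_pos)
    }
  }
})

test_that("annotation passthrough validates coordinates", {
  fx <- generate_assembly_line(2, seed = 3L, docking = FALSE)
  seq1 <- fx$genes$protein[1]
  ann <- data.frame(domain_class = c("KS", "ACP"),
                    start_aa = c(10L, 200L), end_aa = c(60L, 260L))
  hits <- scan_domains(seq1, annotations = ann)
  expect_equal(unique(hits$source), "annotation")
  expect_equal(nrow(hits), 2L)
  ann$end_aa[2] <- nchar(seq1) + 50L
  expect_error(scan_domains(seq1, annotations = ann), "outside")
})

test_that("shuffled residues of the same composition yield no hits", {
  fx <- generate_assembly_line(2, seed = 9L, docking = FALSE)
  chars <- strsplit(fx$genes$protein[1], "")[[1]]
  zero <- 0L
  for (seed in 1:100) {
    shuf <- withr::with_seed(seed, paste(sample(chars), collapse = ""))
    if (nrow(scan_domains(shuf)) == 0L) zero <- zero + 1L
  }
  expect_gte(zero, 95L)
})

test_that("AT substrate calls follow the specificity window", {
  at_mm <- paste0(pad(30), "GHSQG", pad(25), "YASH", pad(30))
  at_mal <- paste0(pad(30), "GHSQG", pad(25), "HAFH", pad(30))
  expect_equal(classify_at_substrate(at_mm)$substrate, "methylmalonyl")
  expect_equal(classify_at_substrate(at_mal)$substrate, "malonyl")
  # unmatched window and missing active site are unknown, with evidence
  other <- paste0(pad(30), "GHSQG", pad(25), "AAAA", pad(30))
  expect_equal(classify_at_substrate(other)$substrate, "unknown")
  no_site <- pad(90)
  call <- classify_at_substrate(no_site)
  expect_equal(call$substrate, "unknown")
  expect_equal(call$evidence, "no_active_site_motif")
  short <- paste0(pad(10), "GHSQG", pad(5))
  expect_equal(classify_at_substrate(short)$evidence,
               "window_out_of_range")
  # calls are single-valued: never both substrates for one input
  for (region in c(at_mm, at_mal, other)) {
    expect_length(classify_at_substrate(region)$substrate, 1L)
  }
})

kr_region <- function(motif = "LDD", tyr = "YLLAN") {
  # anchor at 31, catalytic Y...N at 45, typing motif at 60 (in-window)
  paste0(pad(30), "GGTGTLG", pad(7), tyr, pad(10), motif, pad(40))
}

test_that("KR typing: the (L/V)D(D/N) motif family is B-type giving R", {
  for (motif in c("LDD", "VDN", "LDN", "VDD")) {
    call <- classify_kr_type(kr_region(motif))
    expect_equal(call$kr_type, "B")
    expect_equal(call$beta_oh_config, "R")
    expect_equal(call$motif, motif)
  }
  # A-type tryptophan criterion (extrapolated rule) gives S
  a <- classify_kr_type(kr_region("W"))
  expect_equal(a$kr_type, "A")
  expect_equal(a$beta_oh_config, "S")
  expect_match(a$evidence, "extrapolated")
  # failed catalytic tyrosine rule: inactive, no stereochemistry
  inact <- classify_kr_type(kr_region("LDD", tyr = "FLLAF"))
  expect_equal(inact$kr_type, "inactive")
  expect_equal(inact$beta_oh_config, "none")
  # neither motif: unknown
  expect_equal(classify_kr_type(kr_region("AAA"))$kr_type, "unknown")
})

test_that("generator KR truth is recovered, including A-type regions", {
  spec <- list(list(at = "malonyl", reductive = "KR", kr_type = "A",
                    te = FALSE),
               list(at = "malonyl", reductive = "KR", kr_type = "B",
                    te = FALSE))
  fx <- generate_assembly_line(2, module_spec = spec, seed = 5L,
                               n_genes = 1L, docking = FALSE, te = FALSE)
  line <- order_assembly_line(fx$genes)
  ext <- extension_modules(line)
  expect_equal(ext[[1]]$kr_call$kr_type, "A")
  expect_equal(ext[[1]]$kr_call$beta_oh_config, "S")
  expect_equal(ext[[2]]$kr_call$kr_type, "B")
  expect_equal(ext[[2]]$kr_call$beta_oh_config, "R")
})

test_that("catalytic-activity checks and single-residue ablation locality", {
  fx <- generate_assembly_line(3, seed = 7L)
  line <- order_assembly_line(fx$genes)
  acts_before <- unlist(lapply(line$modules, function(m)
    vapply(m$activity, `[[`, TRUE, "active")))
  expect_true(all(acts_before))

  mut <- mutate_fixture(fx, "ablate_residue", rule = "KS_cys", module = 2)
  line2 <- order_assembly_line(mut$genes)
  flips <- 0L
  for (m in line2$modules) {
    for (nm in names(m$activity)) {
      act <- m$activity[[nm]]
      if (!act$active) {
        flips <- flips + 1L
        expect_equal(m$module_index, 2L)
        expect_equal(act$domain_class, "KS")
        expect_equal(act$missing_residues, "KS_cys")
      }
    }
  }
  expect_equal(flips, 1L)
  expect_error(check_catalytic_activity(
    list(domain_class = "ZZ", start_aa = 1, end_aa = 10, anchor_pos = 1),
    strrep("A", 60)), "unknown domain class")
})

test_that("calls are deterministic for identical sequence and config", {
  fx <- generate_assembly_line(4, seed = 13L)
  h1 <- scan_domains(fx$genes$protein[1])
  h2 <- scan_domains(fx$genes$protein[1])
  expect_identical(h1, h2)
  l1 <- order_assembly_line(fx$genes)
  l2 <- order_assembly_line(fx$genes)
  expect_identical(summary(l1), summary(l2))
})
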