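# Collinearity auditing, trans-module search, iterative enumeration.

test_that("required extensions follow the ring arithmetic", {
  req <- required_extensions(sceliphrolactam_spec())
  expect_equal(req$E_req, 11L)
  expect_equal(req$n_malonyl, 9L)
  expect_equal(req$n_methylmalonyl, 2L)

  st <- starter_unit("3-aminopropionate")
  unit <- data.frame(position = 1, alpha = "H", beta = "ketone",
                     stereo = "none", geometry = "none")
  small <- product_spec_from_units("toy", st, unit)
  expect_equal(required_extensions(small),
               list(E_req = 1L, n_malonyl = 1L, n_methylmalonyl = 0L))

  # E_req always equals the length of the target unit list
  for (seed in 1:20) {
    E <- seed %% 12 + 1
    sp <- product_spec_from_units(
      "rand", starter_unit("3-amino-2-methylpropionate"),
      random_units(E, seed))
    expect_equal(required_extensions(sp)$E_req, E)
    expect_equal(required_extensions(sp)$E_req,
                 nrow(sp$target_units))
  }

  odd <- small
  odd$ring_size <- 7L
  expect_error(required_extensions(odd), "even")
})

test_that("the sce fixture audits one module short of its product", {
  line <- order_assembly_line(sce_fixture()$genes)
  aud <- audit_collinearity(line, sceliphrolactam_spec())
  expect_equal(aud$E_req, 11L)
  expect_equal(aud$M_enc, 10L)
  expect_equal(aud$deficit, 1L)
  expect_equal(aud$verdict, "deficit")
  expect_null(aud$match_table)
})

test_that("matching module counts give collinear or mismatch verdicts", {
  units <- random_units(6, seed = 31)
  st <- starter_unit("3-amino-2-methylpropionate")
  spec <- product_spec_from_units("toy6", st, units)
  fx <- generate_assembly_line(6, module_specs_from_units(units),
                               seed = 31L, te = FALSE)
  line <- order_assembly_line(fx$genes)
  aud <- audit_collinearity(line, spec)
  expect_equal(aud$deficit, 0L)
  expect_equal(aud$verdict, "collinear")
  expect_true(all(aud$match_table$match))

  # flip one target position: same count, mismatch verdict
  units2 <- units
  units2$alpha[3] <- if (units2$alpha[3] == "H") "CH3" else "H"
  spec2 <- product_spec_from_units("toy6b", st, units2)
  aud2 <- audit_collinearity(line, spec2)
  expect_equal(aud2$deficit, 0L)
  expect_equal(aud2$verdict, "mismatch")
  expect_equal(aud2$match_table$position[!aud2$match_table$match], 3)

  # an extra encoded module is an excess verdict
  spec1 <- product_spec_from_units("toy5", st,
                                   random_units(5, seed = 31))
  expect_equal(audit_collinearity(line, spec1)$verdict, "excess")
})

test_that("deleting any module of a homogeneous line always leaves D = 1 recoverable", {
  # fully reduced homogeneous region: every module can stand in for a
  # deleted neighbour, so the hypothesis set is never empty
  units <- data.frame(position = 1:6, alpha = "H", beta = "enoyl",
                      stereo = "none", geometry = "E",
                      stringsAsFactors = FALSE)
  st <- starter_unit("3-amino-2-methylpropionate")
  spec <- product_spec_from_units("poly", st, units)
  fx <- generate_assembly_line(6, module_specs_from_units(units),
                               seed = 23L, te = FALSE)
  for (k in 1:6) {
    mut <- mutate_fixture(fx, "delete_module", k = k)
    line <- order_assembly_line(mut$genes)
    expect_equal(audit_collinearity(line, spec)$deficit, 1L)
    hyps <- enumerate_iterative_hypotheses(line, spec)
    expect_gt(length(hyps), 0L)
    expect_identical(hypotheses_as_keys(hyps, line),
                     brute_force_iterative(line, spec))
  }
})

test_that("distinct unit states localise the gap to adjacent modules", {
  # heterogeneous states around the gap: the only modules able to emulate
  # the deleted unit (a pass can switch domains off, never gain one) are
  # the two flanking the gap
  units <- data.frame(
    position = 1:6, alpha = "H",
    beta = c("ketone", "enoyl", "enoyl", "hydroxyl", "ketone", "enoyl"),
    stereo = c("none", "none", "none", "R", "none", "none"),
    geometry = c("none", "E", "E", "none", "none", "E"),
    stringsAsFactors = FALSE)
  st <- starter_unit("3-amino-2-methylpropionate")
  spec <- product_spec_from_units("toy", st, units)
  fx <- generate_assembly_line(6, module_specs_from_units(units),
                               seed = 17L, te = FALSE)
  for (k in 2:4) {
    mut <- mutate_fixture(fx, "delete_module", k = k)
    line <- order_assembly_line(mut$genes)
    aud <- audit_collinearity(line, spec)
    expect_equal(aud$deficit, 1L)
    hyps <- enumerate_iterative_hypotheses(line, spec)
    expect_gt(length(hyps), 0L)
    pos <- match(vapply(hyps, `[[`, 0L, "module_index"),
                 vapply(extension_modules(line), `[[`, 0L,
                        "module_index"))
    expect_true(all(pos %in% intersect((k - 1):k, 1:5)))
    expect_identical(hypotheses_as_keys(hyps, line),
                     brute_force_iterative(line, spec))
  }
})

test_that("trans-module search filters on composition and docking", {
  bg <- generate_genome_background(20, seed = 3L)
  expect_length(find_trans_candidates(bg), 0L)

  fx <- sce_fixture()
  with_dock <- mutate_fixture(fx, "inject_orphan_trans",
                              with_docking = TRUE)
  genome <- combine_genes(bg, with_dock$genome_extra)
  found <- find_trans_candidates(genome)
  expect_length(found, 1L)
  expect_equal(found[[1]]$gene_id, with_dock$genome_extra$gene_id[1])
  expect_equal(found[[1]]$kind, "trans_module")
  expect_false(found[[1]]$consistent)

  no_dock <- mutate_fixture(fx, "inject_orphan_trans",
                            with_docking = FALSE)
  genome2 <- combine_genes(bg, no_dock$genome_extra)
  expect_length(find_trans_candidates(genome2, require_docking = TRUE),
                0L)
  # monotonicity: relaxing the docking requirement never shrinks the set
  for (g in list(bg, genome, genome2)) {
    strict <- find_trans_candidates(g, require_docking = TRUE)
    relaxed <- find_trans_candidates(g, require_docking = FALSE)
    expect_gte(length(relaxed), length(strict))
    expect_true(all(vapply(strict, `[[`, "", "gene_id") %in%
                      vapply(relaxed, `[[`, "", "gene_id")))
  }
  # a full multi-module PKS gene is never a trans candidate
  genome3 <- combine_genes(bg, fx$genes)
  expect_length(find_trans_candidates(genome3, require_docking = FALSE),
                0L)
})

test_that("sce iterative enumeration finds exactly the two schemes", {
  line <- order_assembly_line(sce_fixture()$genes)
  spec <- sceliphrolactam_spec()
  hyps <- enumerate_iterative_hypotheses(line, spec)
  expect_length(hyps, 2L)
  genes <- vapply(hyps, `[[`, "", "gene_id")
  expect_setequal(genes, c("sceQ", "sceR"))
  q <- hyps[[which(genes == "sceQ")]]
  r <- hyps[[which(genes == "sceR")]]
  # sceQ scheme: KR acts in the first pass, is off in the second
  expect_true("KR" %in% q$pass_states$pass1)
  expect_false("KR" %in% q$pass_states$pass2)
  # sceR scheme: KR off in the first pass, on in the second
  expect_false("KR" %in% r$pass_states$pass1)
  expect_true("KR" %in% r$pass_states$pass2)
  expect_true(all(vapply(hyps, `[[`, TRUE, "consistent")))
  # self-consistency: each surviving backbone reproduces the target
  for (h in hyps) {
    expect_equal(h$resulting_backbone$alpha, spec$target_units$alpha)
    expect_equal(h$resulting_backbone$beta, spec$target_units$beta)
  }
})

test_that("enumeration equals the brute-force oracle on random deficits", {
  n_checked <- 0L
  for (seed in 1:30) {
    E <- seed %% 5 + 4  # 4..8 extensions
    units <- random_units(E, seed * 13)
    st <- starter_unit("3-amino-2-methylpropionate")
    spec <- product_spec_from_units("rand", st, units)
    fx <- generate_assembly_line(E, module_specs_from_units(units),
                                 seed = seed, te = FALSE)
    k <- seed %% E + 1
    mut <- mutate_fixture(fx, "delete_module", k = k)
    line <- order_assembly_line(mut$genes)
    hyps <- enumerate_iterative_hypotheses(line, spec)
    expect_identical(hypotheses_as_keys(hyps, line),
                     brute_force_iterative(line, spec))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 30L)
})

test_that("only the single-deficit search is implemented", {
  line <- order_assembly_line(sce_fixture()$genes)
  st <- starter_unit("3-amino-2-methylpropionate")
  spec13 <- product_spec_from_units("big", st, random_units(13, 5))
  expect_error(enumerate_iterative_hypotheses(line, spec13),
               "deficit")
  spec10 <- product_spec_from_units("even", st, random_units(10, 5))
  expect_error(enumerate_iterative_hypotheses(line, spec10), "deficit")
})
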