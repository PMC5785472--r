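# Backbone prediction, macrolactamization, tailoring, formulas, masses.

one_module_line <- function(at, reductive, kr_type = NA_character_,
                            seed = 2L) {
  fx <- generate_assembly_line(
    1, module_spec = list(list(at = at, reductive = reductive,
                               kr_type = kr_type, te = FALSE)),
    seed = seed, loading = TRUE, docking = FALSE, te = FALSE)
  order_assembly_line(fx$genes)
}

test_that("module domain content maps to the expected unit state", {
  st <- starter_unit("3-amino-2-methylpropionate")
  bb <- predict_backbone(one_module_line("malonyl", "KR", "B"), st)
  expect_equal(bb$units$alpha, "H")
  expect_equal(bb$units$beta, "hydroxyl")
  expect_equal(bb$units$stereo, "R")  # B-type KR
  expect_null(bb$ring_size)

  bb2 <- predict_backbone(one_module_line("methylmalonyl",
                                          character(0)), st)
  expect_equal(bb2$units$alpha, "CH3")
  expect_equal(bb2$units$beta, "ketone")

  bb3 <- predict_backbone(one_module_line("malonyl", c("KR", "DH"), "B"),
                          st)
  expect_equal(bb3$units$beta, "enoyl")
  expect_equal(bb3$units$geometry, "E")
  bb3z <- predict_backbone(one_module_line("malonyl", c("KR", "DH"), "B"),
                           st, geometry_overrides = c("1" = "Z"))
  expect_equal(bb3z$units$geometry, "Z")

  bb4 <- predict_backbone(
    one_module_line("malonyl", c("KR", "DH", "ER"), "B"), st)
  expect_equal(bb4$units$beta, "methylene")
})

test_that("an unknown AT substrate aborts backbone prediction", {
  # void the specificity window in place
  fx <- generate_assembly_line(
    1, module_spec = list(list(at = "malonyl", reductive = "KR",
                               kr_type = "B", te = FALSE)),
    seed = 2L, loading = TRUE, docking = FALSE, te = FALSE)
  fx$genes$protein[1] <- sub("HAFH", "QQQQ", fx$genes$protein[1],
                             fixed = TRUE)
  broken <- order_assembly_line(fx$genes)
  st <- starter_unit("3-amino-2-methylpropionate")
  expect_error(predict_backbone(broken, st), "unknown AT substrate")
})

test_that("macrolactam ring size is 2E + A, matching the ring-graph walk", {
  st <- starter_unit("3-amino-2-methylpropionate")
  bb <- backbone_from_units(st, random_units(11, seed = 1))
  expect_equal(macrolactamize(bb)$ring_size, 26L)
  bb1 <- backbone_from_units(st, random_units(1, seed = 1))
  expect_equal(macrolactamize(bb1)$ring_size, 6L)
  for (E in c(1:8, 11, 15, 20)) {
    for (A in 2:5) {
      expect_equal(2L * E + A, ring_walk_atoms(E, A))
    }
  }
  empty <- bb
  empty$units <- bb$units[0, ]
  expect_error(macrolactamize(empty), "no extension units")
})

test_that("hand atom-count oracles fix the minimal lactam formulas", {
  # frozen by hand before implementation: a single (H, ketone) extension
  # cyclized onto an A = 4 starter gives a 6-membered lactam with one
  # ring ketone: C5H7NO2 for the methyl-free 3-aminopropionate starter,
  # C6H9NO2 with the 3-amino-2-methylpropionate starter methyl
  unit <- data.frame(position = 1, alpha = "H", beta = "ketone",
                     stereo = "none", geometry = "none")
  bb_plain <- macrolactamize(
    backbone_from_units(starter_unit("3-aminopropionate"), unit))
  expect_equal(format(molecular_formula(bb_plain)), "C5H7NO2")

  st <- starter_unit("3-amino-2-methylpropionate")
  bb_me <- macrolactamize(backbone_from_units(st, unit))
  bb_me$amine_protected <- FALSE
  expect_equal(format(molecular_formula(bb_me)), "C6H9NO2")
})

test_that("tailoring deltas: hydroxylation adds exactly one oxygen", {
  st <- starter_unit("3-aminopropionate")
  for (seed in 1:5) {
    bb <- macrolactamize(backbone_from_units(st, random_units(8, seed)))
    f0 <- molecular_formula(bb)
    f1 <- molecular_formula(apply_tailoring(bb, list(
      list(kind = "hydroxylation", site = "C-9", agent = "p450"))))
    expect_equal(f1[["O"]], f0[["O"]] + 1L)
    common <- setdiff(names(f1), "O")
    expect_equal(unclass(f1)[common], unclass(f0)[common])
  }
})

test_that("amide deprotection removes the configured protecting delta", {
  chem <- load_chem_config()
  st <- starter_unit("3-amino-2-methylpropionate", chem)
  unit <- data.frame(position = 1, alpha = "H", beta = "ketone",
                     stereo = "none", geometry = "none")
  bb <- macrolactamize(backbone_from_units(st, unit))
  f_prot <- molecular_formula(bb)
  bb2 <- apply_tailoring(bb, list(list(kind = "amide_deprotection",
                                       site = "N-1", agent = "sceF")))
  f_free <- molecular_formula(bb2)
  delta <- chem$protecting_groups[[chem$default_protecting_group]]
  for (el in names(delta)) {
    expect_equal(f_prot[[el]] - f_free[[el]], delta[[el]])
  }
  # events apply once; duplicates are an error
  expect_error(apply_tailoring(bb2, list(
    list(kind = "amide_deprotection", site = "N-1", agent = "sceF"))),
    "duplicate")
  # deprotecting a starter that was never protected is an error too
  bb_free <- macrolactamize(backbone_from_units(
    starter_unit("3-aminopropionate"), unit))
  expect_error(apply_tailoring(bb_free, list(
    list(kind = "amide_deprotection", site = "N-1", agent = "sceF"))),
    "unprotected")
  bbh <- apply_tailoring(bb, list(
    list(kind = "hydroxylation", site = "C-2", agent = "x")))
  expect_error(apply_tailoring(bbh, list(
    list(kind = "hydroxylation", site = "C-2", agent = "x"))),
    "duplicate")
})

test_that("graph DBE equals formula DBE on random backbones", {
  starters <- c("3-aminopropionate", "3-amino-2-methylpropionate")
  for (seed in 1:100) {
    st <- starter_unit(starters[seed %% 2 + 1])
    E <- seed %% 9 + 1
    bb <- macrolactamize(backbone_from_units(st, random_units(E, seed)))
    expect_equal(dbe(molecular_formula(bb)), backbone_dbe(bb))
  }
})

test_that("the sce tailoring ledger reaches C28H35NO6 from either scheme", {
  spec <- sceliphrolactam_spec()
  bb <- macrolactamize(backbone_from_units(spec$starter,
                                           spec$target_units))
  bb <- apply_tailoring(bb, spec$tailoring)
  f <- molecular_formula(bb)
  expect_equal(format(f), "C28H35NO6")
  expect_equal(dbe(f), 12)
  expect_equal(backbone_dbe(bb), 12L)
})

test_that("printed calcd adduct masses are reproduced at 4 decimals", {
  # values cross-checked against published calcd m/z tabulations
  expect_equal(monoisotopic_mz(chem_formula(C = 28, H = 35, N = 1,
                                            O = 6), "[M+H]+"),
               482.2542)
  expect_equal(monoisotopic_mz(chem_formula(C = 35, H = 58, O = 11),
                               "[M+H]+"), 655.4057)  # filipin III
  expect_equal(monoisotopic_mz(chem_formula(C = 44, H = 62, N = 2,
                                            O = 10), "[M+Na]+"),
               801.4302)                             # factumycin
  expect_equal(monoisotopic_mz(chem_formula(), "[M+H]+"), 1.0078)
})

test_that("dual-implementation mass agreement and additivity", {
  glucose <- chem_formula(C = 6, H = 12, O = 6)
  expect_equal(monoisotopic_mass(glucose) + oracle_mass(c(Na = 1)),
               oracle_mass(c(C = 6, H = 12, O = 6, Na = 1)),
               tolerance = 1e-6)
  expect_equal(monoisotopic_mz(glucose, "[M+Na]+"),
               round(oracle_mass(c(C = 6, H = 12, O = 6)), 4) +
                 round(oracle_mass(c(Na = 1)), 4))
  for (seed in 1:20) {
    f1 <- withr::with_seed(seed, chem_formula(
      C = sample(1:30, 1), H = sample(1:40, 1), O = sample(0:8, 1)))
    f2 <- withr::with_seed(seed + 100, chem_formula(
      C = sample(1:30, 1), H = sample(1:40, 1), N = sample(0:4, 1)))
    both <- chem_formula(C = f1[["C"]] + f2[["C"]],
                         H = f1[["H"]] + f2[["H"]],
                         O = if ("O" %in% names(f1)) f1[["O"]] else 0,
                         N = if ("N" %in% names(f2)) f2[["N"]] else 0)
    # additivity before rounding
    expect_equal(monoisotopic_mass(both),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9)
    # adduct difference is exactly the tabulated H atom at 4 decimals
    expect_equal(monoisotopic_mz(f1, "[M+H]+") - monoisotopic_mz(f1, "M"),
                 1.0078)
  }
  expect_error(monoisotopic_mass(chem_formula(Zz = 2)), "unknown element")
  expect_error(monoisotopic_mz(chem_formula(C = 1), "[M+K]+"),
               "unknown adduct")
})
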