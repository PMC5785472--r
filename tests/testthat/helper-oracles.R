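# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation they check.

# -- exhaustive per-base coverage counter (occupancy oracle) ---------------
bitvec_coverage <- function(intervals, genome_length) {
  covered <- logical(genome_length)
  for (i in seq_len(nrow(intervals))) {
    covered[intervals$from[i]:intervals$to[i]] <- TRUE
  }
  sum(covered)
}

# -- independently typed monoisotopic mass table (mass oracle) -------------
ORACLE_MASSES <- c(C = 12, H = 1.00782503, N = 14.00307401,
                   O = 15.99491462, Na = 22.98976928)
oracle_mass <- function(counts) {
  sum(unlist(counts) * ORACLE_MASSES[names(counts)])
}

# -- ring-size oracle: walk the macrolactam ring graph atom by atom --------
ring_walk_atoms <- function(E, A) {
  atoms <- "N"                                  # amide nitrogen
  for (i in seq_len(A - 1L)) atoms <- c(atoms, paste0("Cs", i))  # starter
  for (i in seq_len(E)) atoms <- c(atoms, paste0("Ca", i), paste0("Cc", i))
  length(atoms)
}

# -- generator-independent unit-state rule (enumeration oracle) ------------
oracle_unit_key <- function(substrate, active) {
  a <- if (substrate == "methylmalonyl") "CH3" else "H"
  kr <- "KR" %in% active
  dh <- "DH" %in% active
  er <- "ER" %in% active
  b <- if (kr && dh && er) "methylene" else if (kr && dh) "enoyl" else
    if (kr) "hydroxyl" else "ketone"
  paste(a, b)
}

# Brute-force two-pass enumeration over all (module, S1, S2) triples,
# via bitmask subsets; returns the deduplicated set of
# "module|unit-key-sequence" strings for exact set comparison.
brute_force_iterative <- function(line, spec) {
  ext <- extension_modules(line)
  tgt_keys <- paste(spec$target_units$alpha, spec$target_units$beta)
  found <- character()
  for (m in seq_along(ext)) {
    mod <- ext[[m]]
    red <- sort(intersect(mod$domains$domain_class, c("KR", "DH", "ER")))
    nsub <- 2^length(red)
    masks <- lapply(seq_len(nsub) - 1L, function(b)
      red[bitwAnd(b, 2^(seq_along(red) - 1L)) > 0])
    base_keys <- vapply(seq_along(ext), function(i) {
      mi <- ext[[i]]
      oracle_unit_key(mi$at_call$substrate,
                      sort(intersect(mi$domains$domain_class,
                                     c("KR", "DH", "ER"))))
    }, "")
    for (s1 in masks) {
      for (s2 in masks) {
        keys <- c(if (m > 1) base_keys[1:(m - 1)],
                  oracle_unit_key(mod$at_call$substrate, s1),
                  oracle_unit_key(mod$at_call$substrate, s2),
                  if (m < length(ext)) base_keys[(m + 1):length(ext)])
        if (identical(keys, tgt_keys)) {
          found <- c(found, paste(m, paste(keys, collapse = ";"),
                                  sep = "|"))
        }
      }
    }
  }
  sort(unique(found))
}

# package-side hypotheses rendered in the oracle's key space
hypotheses_as_keys <- function(hyps, line) {
  ext <- extension_modules(line)
  pos <- match(vapply(hyps, `[[`, 0L, "module_index"),
               vapply(ext, `[[`, 0L, "module_index"))
  sort(unique(vapply(seq_along(hyps), function(i) {
    bb <- hyps[[i]]$resulting_backbone
    paste(pos[i], paste(paste(bb$alpha, bb$beta), collapse = ";"),
          sep = "|")
  }, "")))
}

# -- shared fixture helpers -------------------------------------------------
combine_genes <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("pks_genes", "data.frame")
  out
}

# module specs whose single-pass prediction reproduces a unit table
module_specs_from_units <- function(units) {
  lapply(seq_len(nrow(units)), function(i) {
    red <- switch(units$beta[i], ketone = character(0), hydroxyl = "KR",
                  enoyl = c("KR", "DH"), methylene = c("KR", "DH", "ER"))
    kr <- if ("KR" %in% red) {
      if (identical(units$stereo[i], "S")) "A" else "B"
    } else NA_character_
    list(at = if (units$alpha[i] == "CH3") "methylmalonyl" else "malonyl",
         reductive = red, kr_type = kr, te = FALSE)
  })
}

random_units <- function(E, seed) {
  withr::with_seed(seed, {
    beta <- sample(c("ketone", "hydroxyl", "enoyl", "methylene"), E,
                   replace = TRUE, prob = c(0.2, 0.2, 0.5, 0.1))
    data.frame(position = seq_len(E),
               alpha = sample(c("H", "CH3"), E, replace = TRUE,
                              prob = c(0.8, 0.2)),
               beta = beta,
               stereo = ifelse(beta == "hydroxyl", "R", "none"),
               geometry = ifelse(beta == "enoyl", "E", "none"),
               stringsAsFactors = FALSE)
  })
}
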