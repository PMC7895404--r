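test_that("single-nucleotide missense enumeration is exact", {
  subs <- enumerate_missense_substitutions()
  expect_equal(nrow(subs), 150L)
  expect_false(any(subs$ref_aa == subs$alt_aa))
  expect_true(all(subs$ref_aa %in% AA_ALPHABET))
  expect_true(all(subs$alt_aa %in% AA_ALPHABET))
  expect_false(anyDuplicated(paste(subs$ref_aa, subs$alt_aa)) > 0)
  # matches an independently coded oracle (Biostrings code table,
  # codon-pair traversal)
  expect_identical(sort(paste(subs$ref_aa, subs$alt_aa)),
                   oracle_missense_pairs())
})

test_that("substitutions reachable from codon GGT match a hand enumeration", {
  # GGT (Gly): AGT>S, CGT>R, TGT>C, GAT>D, GCT>A, GTT>V (third-base changes
  # are synonymous)
  subs <- enumerate_missense_substitutions()
  from_g <- subs[subs$ref_aa == "G", "alt_aa"]
  expect_true(all(c("S", "R", "C", "D", "A", "V") %in% from_g))
  # and Gly cannot reach e.g. Lys or Met in one nucleotide step
  expect_false(any(c("K", "M") %in% from_g))
})

test_that("substitution sampling is sized and seeded correctly", {
  s1 <- sample_substitution_set(1, seed = 5)
  expect_equal(nrow(s1), 150L)
  s2 <- sample_substitution_set(2, seed = 5)
  expect_equal(nrow(s2), 300L)
  expect_identical(sample_substitution_set(2, seed = 5), s2)
  expect_false(identical(sample_substitution_set(2, seed = 6)$upstream,
                         s2$upstream))
  expect_true(all(nchar(s2$upstream) == 14L))
  expect_true(all(nchar(s2$downstream) == 14L))
  # flanks can be cut from supplied proteome sequences
  prot <- paste0(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = "")
  sp <- sample_substitution_set(1, proteome = prot, seed = 2)
  expect_equal(nrow(sp), 150L)
})

test_that("delta-PHBR matrix covers the 150 reachable cells", {
  g <- prototypical_genotype("I")
  ctxs <- sample_substitution_set(3, seed = 7)
  pred <- composition_predictor(baseline = 0.3,
                                weights = c(E = 0.4, V = -0.2))
  mat <- build_delta_phbr_matrix(ctxs, g, pred)
  expect_equal(dim(unclass(mat)), c(20L, 20L))
  expect_equal(sum(!is.na(mat)), 150L)
  expect_true(all(is.na(diag(unclass(mat)[AA_ALPHABET, AA_ALPHABET]))))
  expect_true(all(attr(mat, "counts")[!is.na(mat)] == 3L))
  # planted weights force the sign asymmetry: V->E raises, E->V lowers
  expect_gt(mat["V", "E"], 0)
  expect_lt(mat["E", "V"], 0)
  expect_gt(mat["V", "E"], mat["E", "V"])
  # oracle: recompute one cell's median directly from per-context scores
  sel <- which(ctxs$ref_aa == "V" & ctxs$alt_aa == "E")
  deltas <- vapply(sel, function(i) {
    ctx <- context_row(ctxs, i)
    peps <- unique(c(enumerate_windows(ctx, 8:11),
                     enumerate_windows(ctx, 8:11, use_alt = FALSE)))
    s <- score_mutation(ctx, g, synthesize_ranks(peps, g$alleles, pred))
    s$delta_phbr
  }, numeric(1))
  expect_equal(unname(mat["V", "E"]), stats::median(deltas),
               tolerance = 1e-12)
})

test_that("delta-PHBR matrix is invariant to context order and to a
           mutation-blind predictor", {
  g <- prototypical_genotype("I")
  ctxs <- sample_substitution_set(2, seed = 8)
  pred <- composition_predictor(baseline = 0.3, weights = c(G = 0.1))
  m1 <- build_delta_phbr_matrix(ctxs, g, pred)
  set.seed(411)
  shuffled <- ctxs[sample(nrow(ctxs)), ]
  m2 <- build_delta_phbr_matrix(shuffled, g, pred)
  expect_equal(unclass(m1)[AA_ALPHABET, AA_ALPHABET],
               unclass(m2)[AA_ALPHABET, AA_ALPHABET])
  # zero weights: ranks identical for mutant and wild type -> all medians 0
  # (G-weighted predictor differs at the mutated residue only when G is
  # involved; the fully flat predictor is exactly mutation-blind)
  flat <- composition_predictor(baseline = 0.5)
  m0 <- build_delta_phbr_matrix(ctxs, g, flat)
  expect_true(all(abs(m0[!is.na(m0)]) < 1e-12))
})

test_that("composition regression recovers a planted residue weight", {
  g <- prototypical_genotype("I")
  ctxs <- generate_contexts(600, seed = 21)
  pred <- composition_predictor(baseline = 0.3, weights = c(G = 0.2))
  sc <- score_cohort(ctxs, g, pred)
  reg <- aa_composition_regression(ctxs, as.vector(sc$phbr[1, ]))
  expect_equal(nrow(reg), 20L)
  gly <- reg[reg$aa == "G", ]
  expect_gt(gly$slope, 0)
  expect_true(gly$significant)
  expect_equal(gly$class, "hydrophobic")
  expect_equal(unname(AA_CLASSES[c("S", "K")]), c("polar", "charged"))
})

test_that("composition regression is calibrated under a null predictor", {
  g <- prototypical_genotype("I")
  ctxs <- generate_contexts(600, seed = 22)
  sc <- score_cohort(ctxs, g, hash_predictor(3))
  reg <- aa_composition_regression(ctxs, as.vector(sc$phbr[1, ]))
  expect_lte(sum(reg$significant), 1L)
})

test_that("composition percentages close to 100 and constants go NA", {
  ctxs <- generate_contexts(20, seed = 23, exclude = "W")
  comp <- t(vapply(seq_len(nrow(ctxs)), function(i)
    window_residue_counts(context_row(ctxs, i), 8:11, use_alt = TRUE,
                          exclude_mutated = FALSE), numeric(20)))
  pct <- 100 * comp / rowSums(comp)
  expect_equal(unname(rowSums(pct)), rep(100, 20))
  # W never occurs -> constant zero regressor -> NA slope
  reg <- aa_composition_regression(ctxs, runif(20, 0.5, 2))
  expect_true(is.na(reg$slope[reg$aa == "W"]))
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  p_pkg <- stats::fisher.test(matrix(c(10, 90, 10, 990), 2,
                                     byrow = TRUE))$p.value
  expect_equal(p_pkg, oracle_fisher(10, 90, 10, 990), tolerance = 1e-9)
  set.seed(412)
  for (i in 1:50) {
    a <- sample(0:15, 1); b <- sample(1:60, 1)
    c_ <- sample(0:20, 1); d <- sample(1:300, 1)
    expect_equal(stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                           byrow = TRUE))$p.value,
                 oracle_fisher(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("enrichment scan flags a planted glycine-rich context", {
  # target: 4 glycines within +/-3 of the mutated position, against a
  # glycine-free background (the P-loop construction)
  target <- as_protein_contexts(data.frame(
    mutation_id = "KRASlike_G12D", gene = "KRASlike", ref_aa = "G",
    alt_aa = "D", position = 12,
    upstream = "AAAAAAAAAAAGGV", downstream = "GAGGAAAAAAAAAA",
    stringsAsFactors = FALSE))
  bg <- generate_contexts(60, seed = 31, exclude = "G")
  res <- aa_enrichment_scan(target, rbind(as.data.frame(target),
                                          as.data.frame(bg)))
  gly <- res[res$aa == "G", ]
  expect_gt(gly$fold, 2)
  expect_lt(gly$q_value, 0.05)
  # the mutated residue itself is excluded from the counts: the alternate
  # residue D appears in every window but nowhere in the flanks
  expect_equal(res$count[res$aa == "D"], 0L)
})

test_that("enrichment of a context against itself gives folds of exactly 1", {
  ctx <- generate_contexts(1, seed = 32)
  res <- aa_enrichment_scan(ctx, ctx)
  present <- res[!is.na(res$fold), ]
  expect_true(all(abs(present$fold - 1) < 1e-12))
  expect_false(any(present$q_value < 0.05))
  # residues absent from the background are reported NA, not 0-divided
  absent <- res[is.na(res$fold), ]
  expect_true(all(absent$bg_prop == 0))
})
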