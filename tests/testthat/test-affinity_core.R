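test_that("window enumeration matches the class-specific combinatorics", {
  ctx <- protein_context("M1", "G1", "V", "E", 600,
                         strrep("A", 14), strrep("G", 14))
  expect_length(enumerate_windows(ctx, 8:11), 38L)
  expect_length(enumerate_windows(ctx, 15), 15L)
  # every window contains the mutated residue and has a requested length
  w <- enumerate_windows(ctx, 8:11)
  expect_true(all(grepl("E", w, fixed = TRUE)))
  expect_setequal(unique(nchar(w)), 8:11)
  # wild-type windows substitute the reference residue
  wt <- enumerate_windows(ctx, 8:11, use_alt = FALSE)
  expect_true(all(grepl("V", wt, fixed = TRUE)))
  expect_false(any(grepl("E", wt, fixed = TRUE)))
})

test_that("termini truncation keeps only fully contained windows", {
  # mutation at protein position 1: one placement per length
  ctx <- protein_context("M1", "G1", "M", "T", 1, "", strrep("L", 14))
  w <- enumerate_windows(ctx, 8:11)
  expect_length(w, 4L)
  expect_true(all(substr(w, 1, 1) == "T"))
  # too-short context yields empty with a warning, not an error
  tiny <- protein_context("M2", "G1", "A", "V", 3, "GG", "KK")
  expect_warning(res <- enumerate_windows(tiny, 8:11), "no window")
  expect_length(res, 0L)
  expect_error(enumerate_windows(ctx, c(4, 9)), "8\\.\\.25")
})

test_that("harmonic_phbr matches closed forms and rejects bad input", {
  expect_equal(harmonic_phbr(rep(2, 6)), 2)
  expect_equal(harmonic_phbr(c(1, 3)), 1.5)
  expect_equal(harmonic_phbr(c(0.5, 2, 4)), 3 / (2 + 0.5 + 0.25))
  expect_error(harmonic_phbr(c(1, 0)), "positive")
  expect_error(harmonic_phbr(numeric(0)), "empty")
})

test_that("patient_best_rank is the minimum and errors on missing pairs", {
  rt <- rank_table(c("p1", "p2", "p3"), rep("HLA-A02:01", 3), c(4, 0.2, 9))
  expect_equal(patient_best_rank(c("p1", "p2", "p3"), "HLA-A02:01", rt), 0.2)
  expect_equal(patient_best_rank("p1", "HLA-A02:01", rt), 4)
  expect_error(patient_best_rank("p9", "HLA-A02:01", rt), "p9")
  expect_error(patient_best_rank("p1", "HLA-B07:02", rt), "HLA-B07:02")
})

test_that("score_mutation handles constant ranks and identical tables", {
  ctx <- protein_context("M1", "G1", "V", "E", 600,
                         strrep("A", 14), strrep("G", 14))
  g <- prototypical_genotype("I")
  peps <- unique(c(enumerate_windows(ctx, 8:11),
                   enumerate_windows(ctx, 8:11, use_alt = FALSE)))
  grid <- expand.grid(p = peps, a = g$alleles, stringsAsFactors = FALSE)
  rt <- rank_table(grid$p, grid$a, rep(5, nrow(grid)))
  s <- score_mutation(ctx, g, rt)
  expect_equal(s$phbr, 5)
  expect_equal(s$phbr_wt, 5)
  expect_equal(s$delta_phbr, 0)
  expect_equal(s$n_windows, 38L)
  expect_lte(min(s$pbr_per_allele) - 1e-9, s$phbr)
  expect_lte(s$phbr, max(s$pbr_per_allele) + 1e-9)
})

test_that("PHBR scoring matches a brute-force oracle on random fixtures", {
  set.seed(401)
  pool <- c("HLA-A01:01", "HLA-A02:01", "HLA-B07:02", "HLA-B08:01",
            "HLA-C07:01", "HLA-C07:02", "HLA-C04:01")
  for (rep_i in 1:100) {
    ctx <- random_context_fixture(paste0("F", rep_i))
    lengths <- sort(sample(8:11, sample(2:3, 1)))
    win_m <- suppressWarnings(enumerate_windows(ctx, lengths))
    win_w <- suppressWarnings(enumerate_windows(ctx, lengths,
                                                use_alt = FALSE))
    if (!length(win_m)) next
    alleles <- sample(pool, 6, replace = TRUE)  # duplicates = homozygosity
    g <- genotype(alleles, "I", id = "fix")
    peps <- unique(c(win_m, win_w))
    grid <- expand.grid(p = peps, a = unique(alleles),
                        stringsAsFactors = FALSE)
    rank_df <- data.frame(peptide = grid$p, allele = grid$a,
                          rank = round(runif(nrow(grid), 0.01, 50), 4),
                          stringsAsFactors = FALSE)
    rt <- rank_table(rank_df$peptide, rank_df$allele, rank_df$rank)
    s <- score_mutation(ctx, g, rt, lengths = lengths)
    o <- oracle_score(ctx$upstream, ctx$ref_aa, ctx$alt_aa, ctx$downstream,
                      alleles, rank_df, lengths)
    expect_equal(s$phbr, o$phbr, tolerance = 1e-12)
    expect_equal(s$phbr_wt, o$phbr_wt, tolerance = 1e-12)
    expect_equal(s$delta_phbr, o$delta, tolerance = 1e-12)
    expect_equal(unname(s$pbr_per_allele), o$pbrs, tolerance = 1e-12)
  }
})

test_that("PHBR is bounded by the PBRs and monotone in each rank", {
  set.seed(402)
  for (i in 1:50) {
    pbrs <- runif(6, 0.001, 100)
    h <- harmonic_phbr(pbrs)
    expect_gte(h, min(pbrs) - 1e-12)
    expect_lte(h, max(pbrs) + 1e-12)
    j <- sample(6, 1)
    raised <- pbrs
    raised[j] <- raised[j] * (1 + runif(1, 0, 2))
    expect_gte(harmonic_phbr(raised), h - 1e-12)
  }
})

test_that("score_cohort agrees with per-mutation score_mutation", {
  set.seed(403)
  ctxs <- generate_contexts(8, seed = 9)
  pool <- default_allele_pool("I")
  cs <- cohort_spec(5, rep(0.5, 8), genotype_mode = "pool",
                    allele_pool = pool, seed = 2)
  genos <- sample_genotypes(cs)
  pred <- random_composition_predictor(
    unique(unlist(lapply(genos, function(g) g$alleles))), seed = 5)
  sc <- score_cohort(ctxs, genos, pred)
  expect_equal(dim(sc$phbr), c(5L, 8L))
  for (i in seq_len(nrow(ctxs))) {
    ctx <- context_row(ctxs, i)
    for (p in c(1L, 4L)) {
      g <- genos[[p]]
      peps <- unique(c(enumerate_windows(ctx, 8:11),
                       enumerate_windows(ctx, 8:11, use_alt = FALSE)))
      rt <- synthesize_ranks(peps, g$alleles, pred)
      s <- score_mutation(ctx, g, rt)
      expect_equal(sc$phbr[p, i], s$phbr, tolerance = 1e-12)
      expect_equal(sc$phbr_wt[p, i], s$phbr_wt, tolerance = 1e-12)
    }
  }
})

test_that("genotype validation enforces allele counts", {
  expect_error(genotype(c("a", "b"), "I"), "exactly 6")
  expect_error(genotype(rep("a", 6), "II"), "exactly 10")
  expect_silent(genotype(rep("HLA-A02:01", 6), "I"))
  expect_error(protein_context("x", "g", "V", "V", 1), "differ")
  expect_error(protein_context("x", "g", "B", "V", 1), "alphabet")
  expect_error(protein_context("x", "g", "A", "V", 1, strrep("A", 15)),
               "14 residues")
})
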