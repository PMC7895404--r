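test_that("compare_phbr handles degenerate, exact and shifted cases", {
  # identical distributions -> equal medians, p ~ 1
  inc <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  ph <- matrix(c(2, 2, 2, 2), 2, 2)
  res <- compare_phbr(mutation_matrix(inc), ph)
  expect_equal(res$median_obs, res$median_unobs)
  expect_gt(res$p_value, 0.99)
  # exact small-sample case: obs {3,4,5} vs unobs {1,2} -> p = 0.2
  m <- mutation_matrix(matrix(c(1L, 1L, 1L, 0L, 0L), 1, 5))
  p5 <- matrix(c(3, 4, 5, 1, 2), 1, 5)
  res2 <- compare_phbr(m, p5)
  expect_equal(res2$p_value, 0.2)
  expect_equal(res2$p_value, oracle_wilcoxon(c(3, 4, 5), c(1, 2)))
  # planted shift of +1 at n = 500 per group -> p < 0.01
  set.seed(406)
  inc3 <- matrix(rbinom(1000, 1, 0.5), 20, 50)
  ph3 <- matrix(rnorm(1000, 2, 0.5), 20, 50) + inc3
  expect_lt(compare_phbr(mutation_matrix(inc3), ph3)$p_value, 0.01)
  # empty group errors
  expect_error(compare_phbr(mutation_matrix(matrix(1L, 2, 2)),
                            matrix(1, 2, 2)), "non-empty")
})

test_that("exact Wilcoxon path matches enumeration oracle on random draws", {
  set.seed(407)
  for (i in 1:25) {
    k <- sample(2:5, 1); l <- sample(2:6, 1)
    vals <- sample(seq(0.5, 50, by = 0.5), k + l)  # distinct -> no ties
    inc <- matrix(c(rep(1L, k), rep(0L, l)), 1)
    ph <- matrix(vals, 1)
    expect_equal(compare_phbr(mutation_matrix(inc), ph)$p_value,
                 oracle_wilcoxon(vals[seq_len(k)], vals[k + seq_len(l)]),
                 tolerance = 1e-12)
  }
})

test_that("randomizers conserve the right margins exactly", {
  set.seed(408)
  inc <- matrix(rbinom(600, 1, 0.2), 20, 30)
  mat <- mutation_matrix(inc)
  rp <- randomize_within_patient(mat, seed = 5)
  expect_identical(unname(rowSums(rp$incidence)), unname(rowSums(inc)))
  expect_false(identical(unname(rp$incidence), unname(inc)))
  rm_ <- randomize_within_mutation(mat, seed = 5)
  expect_identical(unname(colSums(rm_$incidence)), unname(colSums(inc)))
  expect_identical(unname(rm_$frequencies), unname(mat$frequencies))
  # determinism and the all-zero fixed point
  expect_identical(randomize_within_patient(mat, 9)$incidence,
                   randomize_within_patient(mat, 9)$incidence)
  z <- mutation_matrix(matrix(0L, 3, 4))
  expect_identical(randomize_within_patient(z, 1)$incidence, z$incidence)
  # a single-carrier row keeps exactly one 1
  one <- mutation_matrix(matrix(c(1L, 0L, 0L), 1, 3))
  expect_equal(sum(randomize_within_patient(one, 2)$incidence), 1L)
})

test_that("bh_fdr matches hand computations and a brute-force oracle", {
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(409)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("glmer fit reduces to plain logistic when RE variance is zero", {
  set.seed(410)
  n <- 400; m <- 20
  ph <- matrix(exp(rnorm(n * m)), n, m)
  y <- matrix(rbinom(n * m, 1, plogis(-2 + 0.5 * log(as.vector(ph)))), n, m)
  fit <- fit_random_intercept_logit(mutation_matrix(y), ph, "patient")
  ref <- stats::glm(as.vector(y) ~ log(as.vector(ph)),
                    family = stats::binomial())
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - stats::coef(ref)[2]) / abs(stats::coef(ref)[2]),
            1e-3)
  expect_true(fit$ci_low <= fit$or_ && fit$or_ <= fit$ci_high)
})

test_that("constant-within-group predictors are reported inestimable", {
  scn <- build_scenario(scenario_spec(n_patients = 120, n_mutations = 25,
                                      genotype_mode = "prototypical",
                                      seed = 3))
  f <- fit_random_intercept_logit(scn$matrix, scn$phbr, "mutation")
  expect_false(f$converged)
  expect_true(is.na(f$beta))
  expect_match(f$message, "inestimable")
  # the reduced-rank fallback is explicit, never silent
  fb <- fit_random_intercept_logit(scn$matrix, scn$phbr, "mutation",
                                   fallback = "glm_cluster")
  expect_false(is.na(fb$or_))
  expect_match(fb$method, "cluster")
})

test_that("leave-one-out requires a meaningful baseline", {
  # a null scenario's baseline OR is ~1 (or below); the normalization by
  # (OR - 1) is then meaningless and the scan must refuse to run
  scn0 <- build_scenario(scenario_spec(n_patients = 150, n_mutations = 20,
                                       n_hotspots = 0,
                                       hotspot_phbr_shift = 0, seed = 704))
  f0 <- fit_random_intercept_logit(scn0$matrix, scn0$phbr, "patient")
  expect_true(f0$ci_low <= 1 && f0$ci_high >= 1)  # no planted signal
  if (f0$or_ <= 1) {
    expect_error(leave_one_out_scan(scn0$matrix, scn0$phbr), "OR > 1")
  }
})

test_that("leave-one-out effect sizes follow the normalization formula", {
  # planted scenario small enough for full refits at nAGQ = 0
  scn <- build_scenario(scenario_spec(n_patients = 400, n_mutations = 30,
                                      n_hotspots = 2,
                                      hotspot_phbr_shift = 0.9, seed = 42))
  loo <- leave_one_out_scan(scn$matrix, scn$phbr, threshold_pct = 1,
                            nAGQ = 0)
  base <- attr(loo, "baseline")
  expect_true(base$or_ > 1)
  expect_equal(loo$effect_pct,
               100 * (base$or_ - loo$or_excluded) / (base$or_ - 1),
               tolerance = 1e-12)
  # the formula at the printed-OR worked example: 1.20 -> 1.13 gives 35%
  expect_equal(100 * (1.20 - 1.13) / (1.20 - 1), 35, tolerance = 1e-12)
  # flagging is strict: effects exactly at the threshold are not flagged
  expect_identical(loo$flagged, !is.na(loo$effect_pct) & loo$effect_pct > 1)
  # both planted hot spots dominate the effect ranking
  top2 <- loo$mutation_id[order(-loo$effect_pct)][1:2]
  expect_setequal(top2, scn$hotspot_ids)
})

test_that("per-allele scan recovers a planted frequency-rank correlation", {
  m <- 120; n <- 150
  alleles <- c("HLA-A01:01", "HLA-A02:01", "HLA-B07:02", "HLA-C07:01")
  planted_hit <- logical(20)
  planted_top <- logical(20)
  for (r in 1:20) {
    freqs <- generate_frequency_spectrum(m, seed = 100 + r)
    set.seed(200 + r)
    pbr <- matrix(exp(rnorm(m * 4, 0, 0.5)), m, 4,
                  dimnames = list(names(freqs), alleles))
    z <- scale(log(freqs))[, 1]
    pbr[, 1] <- exp(0.6 * z + rnorm(m, 0, 0.15))
    mat <- simulate_cohort(cohort_spec(n, freqs, seed = 300 + r))
    sc <- per_allele_scan(mat, pbr, nAGQ = 0)
    planted_hit[r] <- sc$class[1] == "gt1"
    planted_top[r] <- which.max(sc$or_) == 1L
  }
  expect_gte(sum(planted_hit), 18L)
  expect_gte(sum(planted_top), 18L)
})

test_that("per-allele scan on a permuted matrix flags nothing", {
  m <- 120
  freqs <- generate_frequency_spectrum(m, seed = 101)
  set.seed(201)
  pbr <- matrix(exp(rnorm(m * 4, 0, 0.5)), m, 4,
                dimnames = list(names(freqs),
                                c("A1", "A2", "B1", "C1")))
  mat <- simulate_cohort(cohort_spec(150, freqs, seed = 301))
  perm <- randomize_within_patient(mat, seed = 9)
  sc <- per_allele_scan(perm, pbr, nAGQ = 0)
  expect_true(all(sc$class == "ns"))
  # single allele, null data: CI contains 1
  one <- per_allele_scan(perm, pbr[, 1, drop = FALSE], nAGQ = 0)
  expect_true(one$ci_low <= 1 && one$ci_high >= 1)
  # absent alleles are skipped with a warning
  expect_warning(per_allele_scan(perm, pbr, alleles = c("A1", "ZZ"),
                                 nAGQ = 0), "ZZ")
})
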