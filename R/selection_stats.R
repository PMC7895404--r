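# Quantifying and attributing the PHBR difference between observed and
# unobserved mutations: rank tests, matrix randomizations, random-intercept
# logistic models, leave-one-out attribution, per-allele scans, FDR.

as_phbr_mat <- function(phbr) {
  if (inherits(phbr, "phbr_cohort_scores")) return(phbr$phbr)
  if (is.matrix(phbr)) return(phbr)
  stopf("phbr must be a numeric matrix or a phbr_cohort_scores object")
}

check_conformable <- function(matrix, phbr) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  phbr <- as_phbr_mat(phbr)
  if (!all(dim(phbr) == dim(matrix$incidence)))
    stopf("mutation matrix (%d x %d) and PHBR matrix (%d x %d) do not conform",
          nrow(matrix$incidence), ncol(matrix$incidence),
          nrow(phbr), ncol(phbr))
  phbr
}

#' Compare PHBR between observed and unobserved mutations
#'
#' Pools all (patient, mutation) cells, splits them by mutation status, and
#' compares the PHBR distributions with a two-sided Wilcoxon rank-sum test.
#' Small samples (both groups at most 25, no ties) use the exact null
#' distribution; otherwise the tie-corrected normal approximation is used.
#'
#' @param matrix A [mutation_matrix()].
#' @param phbr Patients x mutations PHBR matrix (or `"phbr_cohort_scores"`).
#' @return List with `median_obs`, `median_unobs`, `p_value`, `n_obs`,
#'   `n_unobs`.
#' @export
compare_phbr <- function(matrix, phbr) {
  phbr <- check_conformable(matrix, phbr)
  status <- as.vector(matrix$incidence) == 1L
  obs <- as.vector(phbr)[status]
  unobs <- as.vector(phbr)[!status]
  if (!length(obs) || !length(unobs))
    stopf("both observed and unobserved groups must be non-empty")
  if (min(c(obs, unobs)) == max(c(obs, unobs))) {
    # fully tied data carry no ordering information
    p_value <- 1
  } else {
    exact <- length(obs) <= 25L && length(unobs) <= 25L &&
      !anyDuplicated(c(obs, unobs))
    wt <- suppressWarnings(
      stats::wilcox.test(obs, unobs, alternative = "two.sided",
                         exact = exact, correct = !exact))
    p_value <- wt$p.value
  }
  list(median_obs = stats::median(obs), median_unobs = stats::median(unobs),
       p_value = p_value, n_obs = length(obs), n_unobs = length(unobs))
}

#' Within-patient randomization of the mutation matrix
#'
#' Permutes each patient's row independently, preserving per-patient
#' mutation loads (row sums) exactly while destroying the assignment of
#' events to specific mutations (column sums change).
#'
#' @param matrix A [mutation_matrix()].
#' @param seed Integer seed.
#' @return A new [mutation_matrix()] with recomputed frequencies.
#' @export
randomize_within_patient <- function(matrix, seed = 1L) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  inc <- matrix$incidence
  m <- ncol(inc)
  with_substream(seed, "rand_row", {
    for (i in seq_len(nrow(inc))) inc[i, ] <- inc[i, sample.int(m)]
  })
  mutation_matrix(inc)
}

#' Within-mutation randomization of the mutation matrix
#'
#' Permutes each mutation's column independently, preserving per-mutation
#' carrier counts (column sums, hence frequencies) exactly while scrambling
#' which patients carry them.
#'
#' @inheritParams randomize_within_patient
#' @return A new [mutation_matrix()].
#' @export
randomize_within_mutation <- function(matrix, seed = 1L) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  inc <- matrix$incidence
  n <- nrow(inc)
  with_substream(seed, "rand_col", {
    for (j in seq_len(ncol(inc))) inc[, j] <- inc[sample.int(n), j]
  })
  mutation_matrix(inc)
}

#' Random-intercept logistic regression of mutation status on log PHBR
#'
#' Fits `status ~ ln(PHBR) + (1 | group)` by Laplace-approximated maximum
#' likelihood (`lme4::glmer`), with the random intercept grouped either by
#' patient (controlling per-patient mutation load; the *within-patient*
#' model) or by mutation (controlling per-mutation carrier frequency; the
#' *within-mutation* model). The slope is reported as an odds ratio per unit
#' ln(PHBR) with a 95% Wald confidence interval computed on the log-odds
#' scale and exponentiated.
#'
#' If the predictor is constant within every group (e.g. the within-mutation
#' model on an isogenotypic cohort, where each mutation has one PHBR value),
#' the slope is confounded with the random intercepts; the fit is reported
#' as inestimable (`converged = FALSE`, `NA` estimates) rather than
#' producing a fabricated odds ratio.
#'
#' @param matrix A [mutation_matrix()].
#' @param phbr Patients x mutations PHBR matrix (or `"phbr_cohort_scores"`);
#'   strictly positive.
#' @param grouping `"patient"` or `"mutation"`.
#' @param nAGQ Integration setting passed to `lme4::glmer`: 1 (default) is
#'   the Laplace approximation; 0 uses the faster pseudo-likelihood step
#'   only, useful inside the leave-one-out scan.
#' @param fallback `"none"` (default) or `"glm_cluster"`: an explicit
#'   reduced-rank fallback that fits a plain logistic regression with
#'   cluster-robust (sandwich) standard errors instead of a mixed model.
#'   Never applied silently.
#' @return An object of class `"phbr_fit"`: list with `model`, `beta`, `se`,
#'   `or_`, `ci_low`, `ci_high`, `p_value`, `n_obs`, `n_groups`,
#'   `re_variance`, `converged`, `method` and `message`.
#' @export
fit_random_intercept_logit <- function(matrix, phbr,
                                       grouping = c("patient", "mutation"),
                                       nAGQ = 1,
                                       fallback = c("none", "glm_cluster")) {
  grouping <- match.arg(grouping)
  fallback <- match.arg(fallback)
  phbr <- check_conformable(matrix, phbr)
  if (any(phbr <= 0) || anyNA(phbr)) stopf("PHBR values must be positive")
  inc <- matrix$incidence
  y <- as.vector(inc)
  x <- log(as.vector(phbr))
  g <- if (grouping == "patient") {
    factor(rep(matrix$patients, times = ncol(inc)))
  } else {
    factor(rep(matrix$mutations, each = nrow(inc)))
  }
  model_name <- if (grouping == "patient") "within_patient" else
    "within_mutation"

  # inestimable-slope guard: predictor constant within every group
  gvar <- tapply(x, g, stats::var)
  if (all(is.na(gvar) | gvar < 1e-12) && stats::var(x) > 0 &&
      fallback == "none") {
    return(new_phbr_fit(model_name, NA, NA, length(y), nlevels(g), NA,
                        FALSE, "glmer",
                        "ln(PHBR) constant within every group: slope inestimable"))
  }

  if (fallback == "glm_cluster") {
    return(fit_glm_cluster(y, x, g, model_name))
  }

  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(y ~ x + (1 | g),
                family = stats::binomial(),
                data = data.frame(y = y, x = x, g = g),
                nAGQ = nAGQ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      if (grepl("singular", conditionMessage(m), ignore.case = TRUE))
        invokeRestart("muffleMessage")
    }
  )
  # singular fits (random-effect variance at 0) still count as converged
  lme4_msgs <- unlist(fit@optinfo$conv$lme4)
  lme4_msgs <- lme4_msgs[!grepl("singular", lme4_msgs, ignore.case = TRUE)]
  conv_ok <- length(lme4_msgs) == 0L &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0L)
  real_warn <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  converged <- conv_ok && length(real_warn) == 0L
  beta <- lme4::fixef(fit)[["x"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2L]
  re_var <- as.numeric(lme4::VarCorr(fit)$g[1L])
  new_phbr_fit(model_name, beta, se, length(y), nlevels(g), re_var,
               converged, sprintf("glmer (nAGQ=%g)", nAGQ),
               if (length(real_warn)) paste(real_warn, collapse = "; ")
               else "")
}

new_phbr_fit <- function(model, beta, se, n_obs, n_groups, re_var,
                         converged, method, message = "") {
  or_ <- exp(beta)
  z <- beta / se
  structure(
    list(model = model, beta = beta, se = se, or_ = or_,
         ci_low = exp(beta - 1.959964 * se),
         ci_high = exp(beta + 1.959964 * se),
         p_value = 2 * stats::pnorm(-abs(z)),
         n_obs = n_obs, n_groups = n_groups, re_variance = re_var,
         converged = converged, method = method, message = message),
    class = "phbr_fit"
  )
}

#' @export
print.phbr_fit <- function(x, ...) {
  cat(sprintf("<phbr_fit %s, %s>\n", x$model, x$method))
  if (is.na(x$beta)) {
    cat(sprintf("  inestimable: %s\n", x$message))
  } else {
    cat(sprintf("  OR %.4f (95%% CI %.4f-%.4f), p = %.3g, n = %d, groups = %d\n",
                x$or_, x$ci_low, x$ci_high, x$p_value, x$n_obs, x$n_groups))
    cat(sprintf("  RE variance %.4g; converged: %s\n", x$re_variance,
                x$converged))
    if (nzchar(x$message)) cat(sprintf("  note: %s\n", x$message))
  }
  invisible(x)
}

# Plain logistic regression with cluster-robust (CR0 sandwich) SEs; the
# explicit reduced-rank fallback.
fit_glm_cluster <- function(y, x, g, model_name) {
  fit <- stats::glm(y ~ x, family = stats::binomial())
  X <- stats::model.matrix(fit)
  mu <- stats::fitted(fit)
  bread <- stats::vcov(fit)
  scores <- X * (y - mu)
  meat <- crossprod(rowsum(scores, g))
  V <- bread %*% meat %*% bread
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(V))[2L]
  new_phbr_fit(model_name, beta, se, length(y), nlevels(g), 0,
               fit$converged, "glm + cluster-robust SE",
               "reduced-rank fallback (no random intercept)")
}

#' Leave-one-out attribution of the within-patient odds ratio
#'
#' Refits the within-patient model once per mutation, each time excluding
#' that mutation's column from both matrices, and expresses the resulting
#' odds-ratio drop as a percentage of the maximal possible effect:
#' `effect_pct = 100 * (or_baseline - or_excluded) / (or_baseline - 1)`.
#' Mutations whose effect exceeds `threshold_pct` (strictly) are flagged as
#' weak-affinity drivers. The scan requires a converged baseline fit with
#' `or_baseline > 1`; otherwise the normalization is meaningless and an
#' error is raised.
#'
#' @param matrix A [mutation_matrix()].
#' @param phbr Patients x mutations PHBR matrix.
#' @param threshold_pct Flagging threshold in percent (default 1).
#' @param nAGQ Passed to [fit_random_intercept_logit()] for the baseline and
#'   every refit (the same approximation is used throughout so the
#'   normalization is internally consistent).
#' @param verbose Print progress?
#' @return An object of class `"phbr_loo"`: data frame with columns
#'   `mutation_id`, `or_baseline`, `or_excluded`, `effect_pct`, `converged`,
#'   `flagged`; the baseline fit is attached as attribute `"baseline"`.
#' @export
leave_one_out_scan <- function(matrix, phbr, threshold_pct = 1,
                               nAGQ = 1, verbose = FALSE) {
  phbr <- check_conformable(matrix, phbr)
  base <- fit_random_intercept_logit(matrix, phbr, "patient", nAGQ = nAGQ)
  if (!base$converged || is.na(base$or_) || base$or_ <= 1)
    stopf("leave-one-out scan needs a converged baseline with OR > 1 (got OR = %.4f, converged = %s)",
          base$or_, base$converged)
  m <- length(matrix$mutations)
  or_ex <- rep(NA_real_, m)
  conv <- logical(m)
  for (j in seq_len(m)) {
    sub <- mutation_matrix(matrix$incidence[, -j, drop = FALSE])
    f <- fit_random_intercept_logit(sub, phbr[, -j, drop = FALSE],
                                    "patient", nAGQ = nAGQ)
    or_ex[j] <- f$or_
    conv[j] <- f$converged
    if (verbose)
      message(sprintf("[loo %d/%d] %s OR %.4f", j, m, matrix$mutations[j],
                      f$or_))
  }
  effect <- 100 * (base$or_ - or_ex) / (base$or_ - 1)
  effect[!conv] <- NA_real_
  out <- data.frame(
    mutation_id = matrix$mutations,
    or_baseline = base$or_,
    or_excluded = or_ex,
    effect_pct = effect,
    converged = conv,
    flagged = !is.na(effect) & effect > threshold_pct,
    stringsAsFactors = FALSE
  )
  attr(out, "baseline") <- base
  attr(out, "threshold_pct") <- threshold_pct
  class(out) <- c("phbr_loo", class(out))
  out
}

#' Refit after cumulative exclusion of flagged mutations
#'
#' Removes all flagged columns at once and refits the within-patient model;
#' with the true weak-affinity hot spots removed, the odds ratio is expected
#' to return to 1.
#'
#' @param matrix A [mutation_matrix()].
#' @param phbr Patients x mutations PHBR matrix.
#' @param flagged Character vector of mutation ids to exclude (e.g. the
#'   flagged set from [leave_one_out_scan()]).
#' @param nAGQ Passed to [fit_random_intercept_logit()].
#' @return A `"phbr_fit"`.
#' @export
cumulative_exclusion <- function(matrix, phbr, flagged, nAGQ = 1) {
  phbr <- check_conformable(matrix, phbr)
  keep <- !(matrix$mutations %in% flagged)
  if (!any(keep)) stopf("cannot exclude every mutation")
  sub <- mutation_matrix(matrix$incidence[, keep, drop = FALSE])
  fit_random_intercept_logit(sub, phbr[, keep, drop = FALSE], "patient",
                             nAGQ = nAGQ)
}

#' Per-allele within-patient regression scan
#'
#' Runs the within-patient model once per allele, using that allele's
#' ln(PBR) for each mutation as the predictor, and classifies alleles with
#' odds ratios above/below 1 at the requested false discovery rate
#' (Benjamini-Hochberg over the per-allele p-values).
#'
#' @param matrix A [mutation_matrix()].
#' @param pbr Mutations x alleles PBR matrix (e.g. `pbr_mut` from
#'   [score_cohort()]).
#' @param alleles Alleles to scan; defaults to all columns of `pbr`. Alleles
#'   absent from `pbr` are skipped with a warning.
#' @param fdr FDR level for classification (default 0.05).
#' @param nAGQ Passed to [fit_random_intercept_logit()].
#' @return Data frame with one row per scanned allele: `allele`, `or_`,
#'   `ci_low`, `ci_high`, `p_value`, `q_value`, `converged`, `class`
#'   (`"gt1"`, `"lt1"` or `"ns"`).
#' @export
per_allele_scan <- function(matrix, pbr, alleles = colnames(pbr),
                            fdr = 0.05, nAGQ = 1) {
  stopifnot(inherits(matrix, "mutation_matrix"), is.matrix(pbr))
  missing_a <- setdiff(alleles, colnames(pbr))
  if (length(missing_a)) {
    warnf("skipping allele(s) absent from rank data: %s",
          paste(missing_a, collapse = ", "))
    alleles <- setdiff(alleles, missing_a)
  }
  if (!length(alleles)) stopf("no allele left to scan")
  if (!all(matrix$mutations %in% rownames(pbr)))
    stopf("pbr must have one row per mutation in the matrix")
  n <- nrow(matrix$incidence)
  rows <- lapply(alleles, function(a) {
    x <- pbr[matrix$mutations, a]
    xm <- matrix(rep(x, each = n), nrow = n)
    f <- fit_random_intercept_logit(matrix, xm, "patient", nAGQ = nAGQ)
    data.frame(allele = a, or_ = f$or_, ci_low = f$ci_low,
               ci_high = f$ci_high, p_value = f$p_value,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$class <- ifelse(!out$converged | out$q_value >= fdr, "ns",
                      ifelse(out$or_ > 1, "gt1", "lt1"))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up BH: sorted p-values are scaled by `n / rank` and made
#' monotone from the largest down.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  n <- length(p)
  if (!n) return(numeric(0))
  ord <- order(p)
  scaled <- p[ord] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(pmin(scaled, 1))))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

#' Write regression fits as TSV
#'
#' @param fits A `"phbr_fit"` or list of them.
#' @param path Output path.
#' @export
write_fits <- function(fits, path) {
  if (inherits(fits, "phbr_fit")) fits <- list(fits)
  dt <- data.table::rbindlist(lapply(fits, function(f) {
    data.table::data.table(model = f$model, or_ = f$or_, ci_low = f$ci_low,
                           ci_high = f$ci_high, p_value = f$p_value,
                           n_obs = f$n_obs, converged = f$converged)
  }))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
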