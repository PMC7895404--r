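# Cohort-level PHBR scoring. Equivalent to calling score_mutation() for
# every (mutation, patient) pair, but vectorized: per-allele PBRs are
# computed once per mutation and combined per unique genotype, since the
# PBR depends only on (mutation, allele).

#' Score a set of mutations against a cohort of genotypes
#'
#' Computes the patients x mutations PHBR and wild-type PHBR matrices for a
#' context table and a list of genotypes (one per patient; a single genotype
#' is recycled, giving an isogenotypic cohort). Ranks come either from a
#' [rank_table()] covering all windows and alleles, or from a synthetic
#' predictor, in which case ranks are generated on the fly.
#'
#' @param contexts A context table accepted by [as_protein_contexts()].
#' @param genotypes An `"mhc_genotype"`, or a list of them (one per patient).
#' @param ranks A [rank_table()] or a `"phbr_predictor"`.
#' @param lengths Window lengths; defaults to the class-appropriate set.
#' @return An object of class `"phbr_cohort_scores"`: list with matrices
#'   `phbr`, `phbr_wt`, `delta_phbr` (patients x mutations), per-allele PBR
#'   matrices `pbr_mut`, `pbr_wt` (mutations x alleles), `n_windows`,
#'   `patients`, `mutations`, `genotype_ids` and `mhc_class`.
#' @export
score_cohort <- function(contexts, genotypes, ranks, lengths = NULL) {
  contexts <- as_protein_contexts(contexts)
  if (inherits(genotypes, "mhc_genotype")) genotypes <- list(genotypes)
  stopifnot(length(genotypes) >= 1L,
            all(vapply(genotypes, inherits, logical(1), "mhc_genotype")))
  mhc_class <- genotypes[[1L]]$mhc_class
  if (!all(vapply(genotypes, function(g) g$mhc_class, "") == mhc_class))
    stopf("all genotypes must share one MHC class")
  lengths <- lengths %||% mhc_window_lengths(mhc_class)

  n_mut <- nrow(contexts)
  mids <- contexts$mutation_id
  win <- vector("list", 2L * n_mut)
  for (i in seq_len(n_mut)) {
    ctx <- context_row(contexts, i)
    wm <- enumerate_windows(ctx, lengths, use_alt = TRUE)
    ww <- enumerate_windows(ctx, lengths, use_alt = FALSE)
    if (length(wm))
      win[[2L * i - 1L]] <- data.table::data.table(
        mut = i, variant = "mut", peptide = wm)
    if (length(ww))
      win[[2L * i]] <- data.table::data.table(
        mut = i, variant = "wt", peptide = ww)
  }
  win <- data.table::rbindlist(win[!vapply(win, is.null, logical(1))])
  if (!nrow(win)) stopf("no context produced any peptide window")

  alleles <- unique(normalize_allele(
    unlist(lapply(genotypes, function(g) g$alleles), use.names = FALSE)))
  upep <- unique(win$peptide)

  # ranks for every unique peptide x allele
  rk <- matrix(NA_real_, nrow = length(upep), ncol = length(alleles),
               dimnames = list(NULL, alleles))
  if (inherits(ranks, "phbr_predictor")) {
    for (a in alleles)
      rk[, a] <- predict_ranks(ranks, upep, rep(a, length(upep)))
  } else if (inherits(ranks, "rank_table")) {
    for (a in alleles)
      rk[, a] <- rank_lookup(ranks, upep, rep(a, length(upep)))
  } else stopf("ranks must be a rank_table or a phbr_predictor")

  # per-allele PBR (min over windows), mutations x alleles, per variant
  pep_idx <- match(win$peptide, upep)
  grp <- win$mut + n_mut * (win$variant == "wt")
  pbr_all <- matrix(NA_real_, nrow = 2L * n_mut, ncol = length(alleles),
                    dimnames = list(NULL, alleles))
  idx <- split(seq_len(nrow(win)), grp)
  present <- as.integer(names(idx))
  for (a in alleles) {
    v <- rk[pep_idx, a]
    pbr_all[present, a] <- vapply(idx, function(ii) min(v[ii]), numeric(1))
  }
  pbr_mut <- pbr_all[seq_len(n_mut), , drop = FALSE]
  pbr_wt <- pbr_all[n_mut + seq_len(n_mut), , drop = FALSE]
  rownames(pbr_mut) <- rownames(pbr_wt) <- mids

  # PHBR per unique genotype: n_slots / sum of slot-wise 1/PBR
  gids <- vapply(genotypes, function(g) g$id, "")
  ug <- !duplicated(gids)
  uids <- gids[ug]
  slot_counts <- matrix(0, nrow = length(alleles), ncol = sum(ug),
                        dimnames = list(alleles, uids))
  for (j in which(ug)) {
    tab <- table(normalize_allele(genotypes[[j]]$alleles))
    slot_counts[names(tab), gids[j]] <- as.numeric(tab)
  }
  n_slots <- sum(slot_counts[, 1L])
  phbr_u <- n_slots / ((1 / pbr_mut) %*% slot_counts)
  phbr_wt_u <- n_slots / ((1 / pbr_wt) %*% slot_counts)

  patients <- names(genotypes) %||% sprintf("VP%05d", seq_along(genotypes))
  gcol <- match(gids, uids)
  phbr <- t(phbr_u[, gcol, drop = FALSE])
  phbr_wt <- t(phbr_wt_u[, gcol, drop = FALSE])
  dimnames(phbr) <- dimnames(phbr_wt) <- list(patients, mids)

  n_windows <- integer(n_mut)
  tab <- table(factor(win$mut[win$variant == "mut"], levels = seq_len(n_mut)))
  n_windows <- as.integer(tab)
  names(n_windows) <- mids

  structure(
    list(phbr = phbr, phbr_wt = phbr_wt, delta_phbr = phbr - phbr_wt,
         pbr_mut = pbr_mut, pbr_wt = pbr_wt, n_windows = n_windows,
         patients = patients, mutations = mids, genotype_ids = gids,
         mhc_class = mhc_class),
    class = "phbr_cohort_scores"
  )
}

#' @export
print.phbr_cohort_scores <- function(x, ...) {
  cat(sprintf(
    "<phbr_cohort_scores> %d patients x %d mutations (MHC class %s)\n",
    length(x$patients), length(x$mutations), x$mhc_class))
  cat(sprintf("  median PHBR %.3f, median PHBR_wt %.3f\n",
              stats::median(x$phbr), stats::median(x$phbr_wt)))
  invisible(x)
}

#' Write per-mutation PHBR scores as TSV
#'
#' One row per (patient, mutation) pair with columns `mutation_id`,
#' `genotype_id`, `phbr`, `phbr_wt`, `delta_phbr`, `n_windows`.
#'
#' @param scores A `"phbr_cohort_scores"` object.
#' @param path Output path.
#' @export
write_phbr_scores <- function(scores, path) {
  stopifnot(inherits(scores, "phbr_cohort_scores"))
  long <- data.table::data.table(
    mutation_id = rep(scores$mutations, each = length(scores$patients)),
    genotype_id = rep(scores$genotype_ids, times = length(scores$mutations)),
    phbr = as.vector(scores$phbr),
    phbr_wt = as.vector(scores$phbr_wt),
    delta_phbr = as.vector(scores$delta_phbr),
    n_windows = rep(scores$n_windows, each = length(scores$patients))
  )
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}
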