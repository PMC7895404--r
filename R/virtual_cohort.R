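# Virtual patients: isogenotypic or genotype-pool cohorts with mutations
# drawn independently from observed carrier frequencies.

#' Specify a virtual-patient cohort
#'
#' @param n_patients Number of virtual patients.
#' @param frequencies Named numeric vector of per-mutation carrier
#'   probabilities in `[0, 1]` (names become mutation ids).
#' @param genotype_mode `"prototypical"` (every patient carries the same
#'   fixed genotype) or `"pool"` (two alleles per locus drawn independently
#'   with replacement from per-locus allele frequency tables).
#' @param mhc_class `"I"` or `"II"`.
#' @param alleles Allele vector for prototypical mode; defaults to
#'   [prototypical_genotype()].
#' @param allele_pool Pool mode: named list, locus -> named numeric vector of
#'   allele frequencies summing to 1.
#' @param seed Master seed; all draws run in deterministically derived
#'   substreams, so adding a mutation or locus never perturbs the others.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients, frequencies,
                        genotype_mode = c("prototypical", "pool"),
                        mhc_class = c("I", "II"), alleles = NULL,
                        allele_pool = NULL, seed = 1L) {
  genotype_mode <- match.arg(genotype_mode)
  mhc_class <- match.arg(mhc_class)
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) stopf("n_patients must be >= 1")
  frequencies <- unlist(frequencies)
  if (any(frequencies < 0 | frequencies > 1) || anyNA(frequencies))
    stopf("frequencies must lie in [0, 1]")
  if (is.null(names(frequencies)))
    names(frequencies) <- sprintf("M%04d", seq_along(frequencies))
  if (genotype_mode == "pool") {
    if (is.null(allele_pool)) stopf("pool mode requires allele_pool")
    for (locus in names(allele_pool)) {
      p <- allele_pool[[locus]]
      if (is.null(names(p)) || any(p < 0) ||
          abs(sum(p) - 1) > 1e-8)
        stopf("allele_pool[[%s]] must be named frequencies summing to 1",
              locus)
    }
    need <- if (mhc_class == "I") 3L else 5L
    if (length(allele_pool) != need)
      stopf("class %s pools need %d loci, got %d", mhc_class, need,
            length(allele_pool))
  }
  structure(
    list(n_patients = n_patients, frequencies = frequencies,
         genotype_mode = genotype_mode, mhc_class = mhc_class,
         alleles = alleles, allele_pool = allele_pool,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a virtual-patient mutation matrix
#'
#' Each cell (p, m) is an independent Bernoulli draw with the mutation's
#' specified carrier probability -- the "sampling from a binary 0/1 vector
#' with replacement" construction. Mutations are sampled in per-mutation
#' substreams keyed by mutation id, so results are reproducible and adding
#' a mutation leaves the other columns untouched. The returned matrix
#' carries *realized* frequencies (column sums / n), not the specified ones.
#'
#' @param spec A [cohort_spec()].
#' @return A [mutation_matrix()].
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  m <- length(spec$frequencies)
  inc <- matrix(0L, nrow = n, ncol = m,
                dimnames = list(sprintf("VP%05d", seq_len(n)),
                                names(spec$frequencies)))
  for (j in seq_len(m)) {
    inc[, j] <- with_substream(
      spec$seed, paste0("mut|", names(spec$frequencies)[j]),
      stats::rbinom(n, 1L, spec$frequencies[j]))
  }
  mutation_matrix(inc)
}

#' Draw per-patient MHC genotypes
#'
#' In prototypical mode every patient receives the same fixed genotype
#' (default: the package's [prototypical_genotype()]). In pool mode two
#' alleles per locus are drawn independently with replacement according to
#' the per-locus allele frequencies; duplicated draws encode homozygosity.
#'
#' @param spec A [cohort_spec()].
#' @return List of `"mhc_genotype"` objects, one per patient, named by
#'   patient id.
#' @export
sample_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  if (spec$genotype_mode == "prototypical") {
    g <- if (is.null(spec$alleles)) prototypical_genotype(spec$mhc_class)
    else genotype(spec$alleles, spec$mhc_class, id = "prototype_custom")
    out <- rep(list(g), n)
  } else {
    loci <- names(spec$allele_pool)
    draws <- lapply(loci, function(locus) {
      p <- spec$allele_pool[[locus]]
      a <- with_substream(
        spec$seed, paste0("geno|", locus),
        sample(names(p), size = 2L * n, replace = TRUE, prob = p))
      matrix(a, nrow = n, ncol = 2L)
    })
    out <- vector("list", n)
    for (i in seq_len(n)) {
      alleles <- unlist(lapply(draws, function(d) d[i, ]), use.names = FALSE)
      out[[i]] <- genotype(alleles, spec$mhc_class)
    }
  }
  names(out) <- sprintf("VP%05d", seq_len(n))
  out
}
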