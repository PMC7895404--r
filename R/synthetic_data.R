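# Self-contained synthetic fixtures: random protein contexts, long-tailed
# carrier-frequency spectra, and full planted-hot-spot scenarios that
# exercise every pipeline stage without any external data.

#' Generate random protein contexts
#'
#' Draws `n` contexts with full 14/14 flanks whose residues are sampled from
#' a background amino-acid distribution (uniform by default). Reference and
#' alternate residues are drawn from the same alphabet and always differ.
#'
#' @param n Number of contexts.
#' @param aa_distribution Optional named numeric background frequencies
#'   (normalized internally); uniform when `NULL`.
#' @param seed Master seed.
#' @param exclude Residues to exclude from flanks and ref/alt draws (the
#'   scenario generator reserves a marker residue for hot spots this way).
#' @param prefix Mutation-id prefix.
#' @return A context table (class `"phbr_contexts"`), `n` rows.
#' @export
generate_contexts <- function(n, aa_distribution = NULL, seed = 1L,
                              exclude = character(0), prefix = "GEN") {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stopf("n must be >= 0")
  alphabet <- setdiff(AA_ALPHABET, exclude)
  p <- aa_distribution
  if (!is.null(p)) {
    p <- p[alphabet]
    p[is.na(p)] <- 0
    if (sum(p) <= 0) stopf("aa_distribution has no mass on allowed residues")
    p <- p / sum(p)
  }
  flank <- 14L
  empty <- data.frame(mutation_id = character(0), gene = character(0),
                      ref_aa = character(0), alt_aa = character(0),
                      position = integer(0), upstream = character(0),
                      downstream = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(as_protein_contexts(empty))
  df <- with_substream(seed, "contexts", {
    flanks <- matrix(sample(alphabet, 2L * flank * n, replace = TRUE,
                            prob = p), nrow = n)
    ref <- sample(alphabet, n, replace = TRUE, prob = p)
    alt <- vapply(ref, function(r)
      sample(setdiff(alphabet, r), 1L), "")
    data.frame(
      mutation_id = sprintf("%s%04d", prefix, seq_len(n)),
      gene = sprintf("%sG%04d", prefix, seq_len(n)),
      ref_aa = ref, alt_aa = unname(alt),
      position = flank + 1L,
      upstream = apply(flanks[, seq_len(flank), drop = FALSE], 1,
                       paste0, collapse = ""),
      downstream = apply(flanks[, flank + seq_len(flank), drop = FALSE], 1,
                         paste0, collapse = ""),
      stringsAsFactors = FALSE)
  })
  as_protein_contexts(df)
}

#' Generate a long-tailed carrier-frequency spectrum
#'
#' Produces `n_mutations` carrier frequencies following a power-law decay
#' `max_freq * rank^(-exponent)` with multiplicative lognormal jitter,
#' floored at `floor_freq` and capped at `max_freq`, returned sorted in
#' decreasing order. The defaults (`max_freq = 0.057`, `exponent = 1`,
#' `floor_freq = 5e-4`) emulate a pan-cancer driver spectrum: a handful of
#' hot spots above 1%, a most-frequent mutation near 5.7%, and a long rare
#' tail with a median near 0.06%.
#'
#' @param n_mutations Number of mutations.
#' @param max_freq Cap and head of the spectrum.
#' @param exponent Power-law decay exponent (larger = steeper; in the limit
#'   every frequency hits the floor).
#' @param floor_freq Lower clamp.
#' @param jitter_sd Lognormal jitter standard deviation (0 disables).
#' @param seed Master seed.
#' @return Numeric vector of frequencies, decreasing, named `M0001`...
#' @export
generate_frequency_spectrum <- function(n_mutations, max_freq = 0.057,
                                        exponent = 1, floor_freq = 5e-4,
                                        jitter_sd = 0.15, seed = 1L) {
  n_mutations <- as.integer(n_mutations)
  stopifnot(n_mutations >= 1L, max_freq > 0, max_freq <= 1,
            floor_freq > 0, floor_freq <= max_freq)
  base <- max_freq * seq_len(n_mutations)^(-exponent)
  jit <- if (jitter_sd > 0) {
    with_substream(seed, "freqs",
                   exp(stats::rnorm(n_mutations, 0, jitter_sd)))
  } else rep(1, n_mutations)
  f <- pmin(pmax(base * jit, floor_freq), max_freq)
  f <- sort(f, decreasing = TRUE)
  names(f) <- sprintf("M%04d", seq_len(n_mutations))
  f
}

#' Default per-locus allele pools for genotype sampling
#'
#' Small allele-frequency tables (three alleles per class I locus, two per
#' class II locus) built around the prototypical genotype, used by scenario
#' generation in pool mode.
#'
#' @param mhc_class `"I"` or `"II"`.
#' @return Named list, locus -> named frequency vector summing to 1.
#' @export
default_allele_pool <- function(mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  if (mhc_class == "I") {
    list(
      "HLA-A" = c("HLA-A02:01" = 0.45, "HLA-A01:01" = 0.35,
                  "HLA-A03:01" = 0.20),
      "HLA-B" = c("HLA-B07:02" = 0.40, "HLA-B08:01" = 0.35,
                  "HLA-B44:02" = 0.25),
      "HLA-C" = c("HLA-C07:01" = 0.40, "HLA-C07:02" = 0.35,
                  "HLA-C04:01" = 0.25)
    )
  } else {
    list(
      "HLA-DPA" = c("HLA-DPA10103" = 0.6, "HLA-DPA10201" = 0.4),
      "HLA-DPB" = c("HLA-DPB10201" = 0.55, "HLA-DPB10401" = 0.45),
      "HLA-DQA" = c("HLA-DQA10102" = 0.55, "HLA-DQA10501" = 0.45),
      "HLA-DQB" = c("HLA-DQB10301" = 0.55, "HLA-DQB10202" = 0.45),
      "HLA-DRB" = c("HLA-DRB10701" = 0.5, "HLA-DRB11501" = 0.5)
    )
  }
}

#' Specify a planted-hot-spot scenario
#'
#' A scenario is the stated world for pipeline testing: a cohort of virtual
#' patients, a long-tailed mutation frequency spectrum whose top
#' `n_hotspots` mutations ("hot spots") carry a planted ln-PHBR elevation,
#' and a composition predictor that realizes the elevation at the peptide
#' level (the hot-spot alternate residue is a reserved marker residue with
#' a positive rank weight on every allele, so the whole window/PBR/PHBR
#' path is exercised; PHBR values are never edited post hoc).
#'
#' @param n_patients,n_mutations Cohort dimensions (defaults 2000 x 200).
#' @param n_hotspots Number of planted weak-affinity hot spots (default 5),
#'   assigned the top carrier frequencies.
#' @param hotspot_phbr_shift Planted elevation of ln(PHBR) for hot-spot
#'   mutations (default 0.7).
#' @param genotype_mode `"pool"` (default; patients draw genotypes from
#'   [default_allele_pool()], so PHBR varies within mutations and both
#'   regression models are estimable) or `"prototypical"` (isogenotypic).
#' @param mhc_class `"I"` or `"II"`.
#' @param seed Master seed.
#' @param max_freq,exponent,floor_freq,jitter_sd Passed to
#'   [generate_frequency_spectrum()].
#' @param baseline_log10,weight_sd Predictor parameters passed to
#'   [random_composition_predictor()].
#' @param hotspot_marker Reserved residue carried by hot-spot mutations as
#'   their alternate amino acid (default `"E"`, echoing phospho-mimicking
#'   glutamate substitutions); excluded from all other draws.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(n_patients = 2000L, n_mutations = 200L,
                          n_hotspots = 5L, hotspot_phbr_shift = 0.7,
                          genotype_mode = c("pool", "prototypical"),
                          mhc_class = c("I", "II"), seed = 1L,
                          max_freq = 0.057, exponent = 1, floor_freq = 5e-4,
                          jitter_sd = 0.15, baseline_log10 = 0.3,
                          weight_sd = 0.15, hotspot_marker = "E") {
  genotype_mode <- match.arg(genotype_mode)
  mhc_class <- match.arg(mhc_class)
  stopifnot(n_hotspots >= 0L, n_hotspots <= n_mutations,
            hotspot_marker %in% AA_ALPHABET)
  structure(
    list(n_patients = as.integer(n_patients),
         n_mutations = as.integer(n_mutations),
         n_hotspots = as.integer(n_hotspots),
         hotspot_phbr_shift = hotspot_phbr_shift,
         genotype_mode = genotype_mode, mhc_class = mhc_class,
         seed = as.integer(seed), max_freq = max_freq, exponent = exponent,
         floor_freq = floor_freq, jitter_sd = jitter_sd,
         baseline_log10 = baseline_log10, weight_sd = weight_sd,
         hotspot_marker = hotspot_marker),
    class = "scenario_spec"
  )
}

#' Build a full synthetic scenario
#'
#' Realizes a [scenario_spec()]: generates contexts (hot spots receive the
#' marker residue as alternate amino acid; all other draws exclude it),
#' builds the composition predictor whose marker weight equals
#' `hotspot_phbr_shift / ln(10)` (so every mutant window of a hot spot, and
#' hence its PBR on every allele and its PHBR, is elevated by exactly
#' `hotspot_phbr_shift` on the ln scale relative to the unplanted context),
#' samples genotypes and the mutation matrix, and scores the cohort.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `"phbr_scenario"`: list with `matrix`
#'   ([mutation_matrix()]), `scores` ([score_cohort()] output), `phbr`,
#'   `phbr_wt` (matrices), `contexts`, `genotypes`, `frequencies`,
#'   `hotspot_ids`, `predictor` and `spec`.
#' @export
build_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  freqs <- generate_frequency_spectrum(
    spec$n_mutations, spec$max_freq, spec$exponent, spec$floor_freq,
    spec$jitter_sd, seed = spec$seed)
  contexts <- generate_contexts(spec$n_mutations, seed = spec$seed,
                                exclude = spec$hotspot_marker,
                                prefix = "MUT")
  contexts$mutation_id <- names(freqs)
  hotspot_ids <- head(names(freqs), spec$n_hotspots)
  if (spec$n_hotspots > 0L) {
    hs <- seq_len(spec$n_hotspots)
    contexts$alt_aa[hs] <- spec$hotspot_marker
  }
  contexts <- as_protein_contexts(contexts)

  cspec <- cohort_spec(
    spec$n_patients, freqs, genotype_mode = spec$genotype_mode,
    mhc_class = spec$mhc_class,
    allele_pool = if (spec$genotype_mode == "pool")
      default_allele_pool(spec$mhc_class) else NULL,
    seed = spec$seed)
  genotypes <- sample_genotypes(cspec)
  all_alleles <- unique(unlist(lapply(genotypes, function(g) g$alleles)))

  planted <- stats::setNames(spec$hotspot_phbr_shift / log(10),
                             spec$hotspot_marker)
  predictor <- random_composition_predictor(
    all_alleles, seed = spec$seed, baseline = spec$baseline_log10,
    weight_sd = spec$weight_sd, planted_weights = planted)

  scores <- score_cohort(contexts, genotypes, predictor)
  mat <- simulate_cohort(cspec)

  structure(
    list(matrix = mat, scores = scores, phbr = scores$phbr,
         phbr_wt = scores$phbr_wt, contexts = contexts,
         genotypes = genotypes, frequencies = freqs,
         hotspot_ids = hotspot_ids, predictor = predictor, spec = spec),
    class = "phbr_scenario"
  )
}

#' @export
print.phbr_scenario <- function(x, ...) {
  cat(sprintf(
    "<phbr_scenario> %d patients x %d mutations, %d hot spot(s), shift %.2f (%s genotypes)\n",
    x$spec$n_patients, x$spec$n_mutations, x$spec$n_hotspots,
    x$spec$hotspot_phbr_shift, x$spec$genotype_mode))
  invisible(x)
}

#' Write all scenario inputs as plain-text files
#'
#' Writes the standard input files for a scenario into a directory:
#' `contexts.tsv`, `matrix.tsv` (binary incidence with patient ids),
#' `frequencies.tsv`, `ranks.tsv` (the full rank table the predictor
#' implies) and `genotypes.json`.
#'
#' @param scenario A `"phbr_scenario"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "phbr_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(scenario$contexts, file.path(dir, "contexts.tsv"),
                     sep = "\t")
  inc <- data.table::as.data.table(scenario$matrix$incidence,
                                   keep.rownames = "patient_id")
  data.table::fwrite(inc, file.path(dir, "matrix.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(mutation_id = names(scenario$frequencies),
                           frequency = scenario$frequencies),
    file.path(dir, "frequencies.tsv"), sep = "\t")
  windows <- unique(unlist(lapply(seq_len(nrow(scenario$contexts)),
    function(i) {
      ctx <- context_row(scenario$contexts, i)
      c(enumerate_windows(ctx, mhc_window_lengths(scenario$spec$mhc_class),
                          use_alt = TRUE),
        enumerate_windows(ctx, mhc_window_lengths(scenario$spec$mhc_class),
                          use_alt = FALSE))
    })))
  alleles <- unique(unlist(lapply(scenario$genotypes,
                                  function(g) g$alleles)))
  write_rank_table(synthesize_ranks(windows, alleles, scenario$predictor),
                   file.path(dir, "ranks.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    gl <- lapply(scenario$genotypes, function(g)
      list(id = g$id, mhc_class = g$mhc_class, alleles = g$alleles))
    writeLines(jsonlite::toJSON(gl, auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "genotypes.json"))
  }
  invisible(dir)
}
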