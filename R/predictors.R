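# Synthetic rank predictors: deterministic stand-ins for external affinity
# prediction tools. They reproduce the *structure* of predictor output
# (peptide x allele percentile ranks), never real binding affinities.

#' Deterministic pseudo-random ("hash") rank predictor
#'
#' Maps every (peptide, allele) pair to a uniform-like rank in
#' `[0.001, 100]` via an integer string hash, so the same seed always yields
#' byte-identical rank tables on every platform. Useful as an exchangeable
#' null predictor.
#'
#' @param seed Integer seed mixed into the hash.
#' @return A `"phbr_predictor"` of kind `"hash"`.
#' @export
hash_predictor <- function(seed = 1L) {
  structure(list(kind = "hash", seed = as.integer(seed)),
            class = "phbr_predictor")
}

#' Composition-based rank predictor
#'
#' Generates ranks from peptide amino-acid composition on the log scale:
#' `log10(rank) = baseline + sum_j m_j * w(aa_j)` over window positions `j`,
#' where `m_j` is `anchor_multiplier` at anchor positions and 1 elsewhere,
#' and `w` is a per-residue weight. Ranks are clipped to `[0.001, 100]`.
#' Positive weights make a residue unfavourable for presentation (higher
#' rank), letting tests plant composition effects such as rank-raising
#' glutamates or glycine-rich contexts.
#'
#' @param baseline Scalar, or named numeric per allele, on the log10-rank
#'   scale.
#' @param weights Named numeric vector of per-residue weights (missing
#'   residues default to 0), or a named list of such vectors keyed by allele.
#' @param anchor_positions Integer window offsets (1-based) whose residues
#'   are scaled by `anchor_multiplier`.
#' @param anchor_multiplier Scalar multiplier at anchor positions.
#' @param seed Integer tag carried for provenance (the predictor itself is
#'   fully deterministic).
#' @return A `"phbr_predictor"` of kind `"composition"`.
#' @export
composition_predictor <- function(baseline = 0, weights = numeric(0),
                                  anchor_positions = integer(0),
                                  anchor_multiplier = 1, seed = 1L) {
  structure(list(kind = "composition", seed = as.integer(seed),
                 baseline = baseline, weights = weights,
                 anchor_positions = as.integer(anchor_positions),
                 anchor_multiplier = anchor_multiplier),
            class = "phbr_predictor")
}

#' Randomized per-allele composition predictor
#'
#' Draws independent per-allele residue weights and baselines (seeded, hence
#' reproducible), then overlays `planted_weights` identically on every
#' allele. This is the scenario generator's workhorse: the random weights
#' give each allele its own preferences (so PHBR varies across genotypes)
#' while a planted weight produces a controlled, allele-wide rank shift for
#' peptides carrying a marker residue.
#'
#' @param alleles Character vector of allele names.
#' @param seed Master seed.
#' @param baseline Mean baseline on the log10-rank scale; per-allele
#'   baselines are jittered uniformly within `+/- baseline_jitter`.
#' @param baseline_jitter Half-width of the baseline jitter.
#' @param weight_sd Standard deviation of the per-residue weights.
#' @param planted_weights Named numeric vector overriding specific residue
#'   weights on all alleles (e.g. `c(E = 0.3)`).
#' @return A `"phbr_predictor"` of kind `"composition"` with per-allele
#'   parameters.
#' @export
random_composition_predictor <- function(alleles, seed = 1L, baseline = 0.3,
                                         baseline_jitter = 0.15,
                                         weight_sd = 0.08,
                                         planted_weights = numeric(0)) {
  alleles <- normalize_allele(alleles)
  baselines <- stats::setNames(numeric(length(alleles)), alleles)
  weights <- vector("list", length(alleles))
  names(weights) <- alleles
  for (a in alleles) {
    w <- with_substream(seed, paste0("pred_w|", a),
                        stats::rnorm(length(AA_ALPHABET), 0, weight_sd))
    names(w) <- AA_ALPHABET
    if (length(planted_weights)) w[names(planted_weights)] <- planted_weights
    weights[[a]] <- w
    baselines[a] <- baseline +
      with_substream(seed, paste0("pred_b|", a),
                     stats::runif(1, -baseline_jitter, baseline_jitter))
  }
  composition_predictor(baseline = baselines, weights = weights, seed = seed)
}

#' @export
print.phbr_predictor <- function(x, ...) {
  cat(sprintf("<phbr_predictor kind=%s seed=%d>\n", x$kind, x$seed))
  invisible(x)
}

# Per-allele weight vector over the full alphabet (absent residues -> 0).
predictor_weights <- function(pred, allele) {
  w <- if (is.list(pred$weights)) {
    pred$weights[[allele]] %||% stopf("no weights for allele %s", allele)
  } else pred$weights
  full <- stats::setNames(numeric(length(AA_ALPHABET)), AA_ALPHABET)
  if (length(w)) full[names(w)] <- w
  full
}

predictor_baseline <- function(pred, allele) {
  b <- pred$baseline
  if (!is.null(names(b))) {
    if (!allele %in% names(b)) stopf("no baseline for allele %s", allele)
    unname(b[allele])
  } else as.numeric(b)
}

# Pairwise rank prediction for parallel (peptide, allele) vectors.
predict_ranks <- function(pred, peptides, alleles) {
  stopifnot(inherits(pred, "phbr_predictor"),
            length(peptides) == length(alleles))
  alleles <- normalize_allele(alleles)
  n <- length(peptides)
  out <- numeric(n)
  if (pred$kind == "hash") {
    h <- str_hash(paste0(peptides, "|", alleles), seed = pred$seed)
    u <- (h + 0.5) / 2147483647
    out <- pmin(pmax(u * RANK_CEIL, RANK_FLOOR), RANK_CEIL)
    return(out)
  }
  # composition: batch by (length, allele) and score via a codes matrix
  len <- nchar(peptides)
  aa_index <- stats::setNames(seq_along(AA_ALPHABET), AA_ALPHABET)
  for (k in unique(len)) {
    sel_k <- which(len == k)
    codes <- matrix(
      aa_index[unlist(strsplit(peptides[sel_k], ""), use.names = FALSE)],
      nrow = length(sel_k), ncol = k, byrow = TRUE)
    if (anyNA(codes)) stopf("peptides may only contain the 20-letter alphabet")
    mult <- rep(1, k)
    anch <- pred$anchor_positions[pred$anchor_positions <= k]
    mult[anch] <- pred$anchor_multiplier
    for (a in unique(alleles[sel_k])) {
      sel <- sel_k[alleles[sel_k] == a]
      w <- predictor_weights(pred, a)
      wm <- matrix(w[codes[alleles[sel_k] == a, , drop = FALSE]],
                   ncol = k)
      log10rank <- predictor_baseline(pred, a) + as.vector(wm %*% mult)
      out[sel] <- pmin(pmax(10^log10rank, RANK_FLOOR), RANK_CEIL)
    }
  }
  out
}

#' Synthesize a rank table for a peptide and allele set
#'
#' Evaluates a synthetic predictor on the full peptide-by-allele cross
#' product. Identical calls with the same predictor always return identical
#' tables.
#'
#' @param peptides Character vector of peptides.
#' @param alleles Character vector of alleles.
#' @param spec A `"phbr_predictor"` from [hash_predictor()],
#'   [composition_predictor()] or [random_composition_predictor()].
#' @return A [rank_table()].
#' @export
synthesize_ranks <- function(peptides, alleles, spec) {
  peptides <- unique(as.character(peptides))
  alleles <- unique(normalize_allele(alleles))
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      stringsAsFactors = FALSE)
  rank_table(grid$peptide, grid$allele,
             predict_ranks(spec, grid$peptide, grid$allele))
}
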