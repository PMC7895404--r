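# The single-nucleotide-reachable missense substitution space and its
# consequences for peptide presentation: the 20x20 median-dPHBR matrix,
# amino-acid composition regression and per-mutation enrichment.

#' Enumerate single-nucleotide-reachable missense substitutions
#'
#' Brute-forces all 64 codons x 3 positions x 3 alternative bases of the
#' standard genetic code and collects every distinct ordered
#' (reference, mutated) amino-acid pair that is non-synonymous and involves
#' no stop codon. Exactly 150 such substitution types exist.
#'
#' @return Data frame with one row per substitution type: `ref_aa`,
#'   `alt_aa`, `n_codon_paths` (number of distinct single-base codon changes
#'   realizing the type) and `example_path` (one witness,
#'   `"GTG>GAG@2"`-style). Ordered by `ref_aa`, then `alt_aa`.
#' @export
enumerate_missense_substitutions <- function() {
  code <- GENETIC_CODE_DNA
  codons <- names(code)
  recs <- list()
  for (cod in codons) {
    ref <- code[[cod]]
    if (ref == "*") next
    for (pos in 1:3) {
      for (b in setdiff(DNA_BASES, substr(cod, pos, pos))) {
        alt_cod <- cod
        substr(alt_cod, pos, pos) <- b
        alt <- code[[alt_cod]]
        if (alt == "*" || alt == ref) next
        recs[[length(recs) + 1L]] <- data.frame(
          ref_aa = ref, alt_aa = alt,
          path = sprintf("%s>%s@%d", cod, alt_cod, pos),
          stringsAsFactors = FALSE)
      }
    }
  }
  all_paths <- do.call(rbind, recs)
  key <- paste(all_paths$ref_aa, all_paths$alt_aa)
  first <- !duplicated(key)
  out <- data.frame(
    ref_aa = all_paths$ref_aa[first],
    alt_aa = all_paths$alt_aa[first],
    n_codon_paths = as.vector(table(key)[key[first]]),
    example_path = all_paths$path[first],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ref_aa, out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample random protein contexts for every substitution type
#'
#' Draws `per_type` contexts per single-nucleotide-reachable substitution
#' type (150 types; `per_type = 100` gives the canonical 15,000-substitution
#' dataset). Flanking sequences of 14 residues on each side are sampled from
#' a background amino-acid distribution (uniform by default) or, if
#' `proteome` is supplied, cut from random positions of the given protein
#' sequences.
#'
#' @param per_type Contexts per substitution type (>= 1).
#' @param aa_distribution Optional named numeric vector of background
#'   residue frequencies (normalized internally); uniform when `NULL`.
#' @param proteome Optional character vector of protein sequences to cut
#'   flanks from (overrides `aa_distribution`).
#' @param seed Master seed; each substitution type draws from its own
#'   derived substream.
#' @return A context table (class `"phbr_contexts"`).
#' @export
sample_substitution_set <- function(per_type = 100L, aa_distribution = NULL,
                                    proteome = NULL, seed = 1L) {
  per_type <- as.integer(per_type)
  if (is.na(per_type) || per_type < 1L) stopf("per_type must be >= 1")
  types <- enumerate_missense_substitutions()
  flank <- 14L
  rows <- vector("list", nrow(types))
  for (i in seq_len(nrow(types))) {
    ref <- types$ref_aa[i]; alt <- types$alt_aa[i]
    key <- paste0("subst|", ref, alt)
    flanks <- with_substream(seed, key, {
      if (is.null(proteome)) {
        p <- aa_distribution
        if (!is.null(p)) {
          p <- p[AA_ALPHABET]; p[is.na(p)] <- 0; p <- p / sum(p)
        }
        draws <- sample(AA_ALPHABET, size = 2L * flank * per_type,
                        replace = TRUE, prob = p)
        matrix(draws, nrow = per_type)
      } else {
        long <- proteome[nchar(proteome) >= 2L * flank]
        if (!length(long)) stopf("no proteome sequence long enough for flanks")
        out <- matrix("", nrow = per_type, ncol = 2L * flank)
        for (r in seq_len(per_type)) {
          s <- long[sample.int(length(long), 1L)]
          start <- sample.int(nchar(s) - 2L * flank + 1L, 1L)
          out[r, ] <- strsplit(substr(s, start, start + 2L * flank - 1L),
                               "")[[1]]
        }
        out
      }
    })
    up <- apply(flanks[, seq_len(flank), drop = FALSE], 1, paste0,
                collapse = "")
    down <- apply(flanks[, flank + seq_len(flank), drop = FALSE], 1, paste0,
                  collapse = "")
    rows[[i]] <- data.frame(
      mutation_id = sprintf("SIM_%s%s_%04d", ref, alt, seq_len(per_type)),
      gene = "SIMULATED", ref_aa = ref, alt_aa = alt,
      position = flank + 1L, upstream = up, downstream = down,
      stringsAsFactors = FALSE)
  }
  as_protein_contexts(do.call(rbind, rows))
}

#' Build the 20x20 median-dPHBR substitution matrix
#'
#' Scores every context against a genotype, groups the per-context dPHBR
#' (mutant PHBR minus wild-type PHBR) by ordered (reference, mutated)
#' amino-acid pair, and fills a 20x20 matrix with per-cell medians. Cells
#' corresponding to substitution types absent from the input stay `NA`
#' (single-nucleotide-unreachable types are always absent; reachable types
#' without contexts trigger a warning). Rows and columns are ordered by
#' decreasing row/column median.
#'
#' @param contexts A context table (e.g. from [sample_substitution_set()]).
#' @param genotype An `"mhc_genotype"`.
#' @param ranks A [rank_table()] or `"phbr_predictor"`.
#' @return An object of class `"substitution_matrix"`: the 20x20 numeric
#'   matrix with attributes `counts` (per-cell context counts) and
#'   `mhc_class`.
#' @export
build_delta_phbr_matrix <- function(contexts, genotype, ranks) {
  contexts <- as_protein_contexts(contexts)
  scores <- score_cohort(contexts, genotype, ranks)
  delta <- as.vector(scores$delta_phbr[1L, contexts$mutation_id])
  key <- paste(contexts$ref_aa, contexts$alt_aa)
  med <- tapply(delta, key, stats::median)
  cnt <- tapply(delta, key, length)
  mat <- matrix(NA_real_, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  counts <- matrix(0L, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (k in names(med)) {
    pair <- strsplit(k, " ")[[1]]
    mat[pair[1L], pair[2L]] <- med[[k]]
    counts[pair[1L], pair[2L]] <- cnt[[k]]
  }
  reachable <- enumerate_missense_substitutions()
  missing_types <- reachable[is.na(mat[cbind(reachable$ref_aa,
                                             reachable$alt_aa)]), ]
  if (nrow(missing_types))
    warnf("%d reachable substitution type(s) have no context and stay NA",
          nrow(missing_types))
  row_ord <- order(-apply(mat, 1, stats::median, na.rm = TRUE))
  col_ord <- order(-apply(mat, 2, stats::median, na.rm = TRUE))
  mat <- mat[row_ord, col_ord]
  counts <- counts[row_ord, col_ord]
  structure(mat, counts = counts, mhc_class = genotype$mhc_class,
            class = c("substitution_matrix", "matrix", "array"))
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf(
    "<substitution_matrix> 20x20, %d scored cells (MHC class %s)\n",
    sum(!is.na(x)), attr(x, "mhc_class")))
  invisible(x)
}

#' Write a substitution matrix as CSV
#'
#' 20 rows x 20 columns in the stored (median-ranked) order; absent cells
#' are left empty.
#'
#' @param mat A `"substitution_matrix"`.
#' @param path Output path.
#' @export
write_substitution_matrix <- function(mat, path) {
  m <- unclass(mat)
  attr(m, "counts") <- NULL
  attr(m, "mhc_class") <- NULL
  utils::write.csv(m, path, na = "")
  invisible(path)
}

# Residue counts across a context's mutation-containing windows, with
# per-window multiplicity. The mutated position itself is excluded when
# `exclude_mutated` (its residue would otherwise dominate the tally: it
# appears in every window). With `unique_residues = TRUE` each protein
# position is counted once instead (sensitivity-analysis mode).
window_residue_counts <- function(context, lengths = 8:11, use_alt = TRUE,
                                  exclude_mutated = TRUE,
                                  unique_residues = FALSE) {
  x <- if (use_alt) context$alt_aa else context$ref_aa
  seqn <- paste0(context$upstream, x, context$downstream)
  chars <- strsplit(seqn, "")[[1]]
  mpos <- nchar(context$upstream) + 1L
  total <- length(chars)
  counts <- stats::setNames(integer(length(AA_ALPHABET)), AA_ALPHABET)
  seen <- rep(0L, total)
  for (k in sort(unique(as.integer(lengths)))) {
    lo <- max(1L, mpos - k + 1L)
    hi <- min(mpos, total - k + 1L)
    if (hi < lo) next
    for (s in lo:hi) {
      pos <- s:(s + k - 1L)
      seen[pos] <- seen[pos] + 1L
    }
  }
  if (unique_residues) seen <- pmin(seen, 1L)
  if (exclude_mutated) seen[mpos] <- 0L
  tab <- tapply(seen, chars, sum)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Regress log PHBR on amino-acid composition
#'
#' For each of the 20 amino acids, computes its percentage among the
#' residues of every context's mutation-containing windows (with per-window
#' multiplicity, mutated position included) and fits an ordinary
#' least-squares regression of `ln(PHBR)` on that percentage. Slopes are
#' labelled by physicochemical class and tested at the requested FDR across
#' the 20 regressions. Positive slopes mark residues whose abundance raises
#' PHBR (weakens presentation).
#'
#' @param contexts A context table.
#' @param phbr_values Numeric vector of PHBR scores, one per context row.
#' @param lengths Window lengths (default class I, 8--11).
#' @param fdr FDR level (default 0.05).
#' @return Data frame with `aa`, `class`, `slope`, `se`, `p_value`,
#'   `q_value`, `significant`; slope `NA` where the regressor is constant.
#' @export
aa_composition_regression <- function(contexts, phbr_values, lengths = 8:11,
                                      fdr = 0.05) {
  contexts <- as_protein_contexts(contexts)
  stopifnot(length(phbr_values) == nrow(contexts), all(phbr_values > 0))
  comp <- t(vapply(seq_len(nrow(contexts)), function(i) {
    cnt <- window_residue_counts(context_row(contexts, i), lengths,
                                 use_alt = TRUE, exclude_mutated = FALSE)
    100 * cnt / sum(cnt)
  }, numeric(length(AA_ALPHABET))))
  colnames(comp) <- AA_ALPHABET
  y <- log(phbr_values)
  rows <- lapply(AA_ALPHABET, function(aa) {
    x <- comp[, aa]
    if (stats::var(x) < 1e-12) {
      return(data.frame(aa = aa, class = unname(AA_CLASSES[aa]),
                        slope = NA_real_, se = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    f <- stats::summary.lm(stats::lm(y ~ x))
    data.frame(aa = aa, class = unname(AA_CLASSES[aa]),
               slope = f$coefficients[2L, 1L], se = f$coefficients[2L, 2L],
               p_value = f$coefficients[2L, 4L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_fdr(out$p_value[ok])
  out$significant <- !is.na(out$q_value) & out$q_value < fdr
  out
}

#' Amino-acid enrichment around target mutations
#'
#' For each target mutation, counts the residues across its
#' mutation-containing windows (per-window multiplicity, mutated position
#' excluded) and compares each amino acid's proportion to the background
#' proportion pooled over the background contexts, via a two-sided Fisher's
#' exact test on the 2x2 table (this residue vs others, target vs
#' background). Folds are proportion ratios; q-values come from BH across
#' all (mutation, amino acid) tests. Amino acids absent from the background
#' have undefined folds and are reported `NA` without a test.
#'
#' @param target_contexts Context table of mutations to scan.
#' @param background_contexts Context table defining the background
#'   composition (typically the complete dataset).
#' @param lengths Window lengths (default 8--11).
#' @param unique_residues Count each protein position once instead of with
#'   per-window multiplicity (sensitivity-analysis mode).
#' @return Data frame with `mutation_id`, `aa`, `count`, `prop`, `bg_prop`,
#'   `fold`, `p_value`, `q_value`.
#' @export
aa_enrichment_scan <- function(target_contexts, background_contexts,
                               lengths = 8:11, unique_residues = FALSE) {
  target_contexts <- as_protein_contexts(target_contexts)
  background_contexts <- as_protein_contexts(background_contexts)
  if (!nrow(background_contexts)) stopf("background must be non-empty")
  bg <- Reduce(`+`, lapply(seq_len(nrow(background_contexts)), function(i)
    window_residue_counts(context_row(background_contexts, i), lengths,
                          use_alt = TRUE, exclude_mutated = TRUE,
                          unique_residues = unique_residues)))
  bg_tot <- sum(bg)
  rows <- list()
  for (i in seq_len(nrow(target_contexts))) {
    cnt <- window_residue_counts(context_row(target_contexts, i), lengths,
                                 use_alt = TRUE, exclude_mutated = TRUE,
                                 unique_residues = unique_residues)
    tot <- sum(cnt)
    for (aa in AA_ALPHABET) {
      if (bg[aa] == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          mutation_id = target_contexts$mutation_id[i], aa = aa,
          count = cnt[[aa]], prop = cnt[[aa]] / tot, bg_prop = 0,
          fold = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
        next
      }
      tab <- matrix(c(cnt[[aa]], tot - cnt[[aa]],
                      bg[[aa]], bg_tot - bg[[aa]]), nrow = 2L, byrow = TRUE)
      p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        mutation_id = target_contexts$mutation_id[i], aa = aa,
        count = cnt[[aa]], prop = cnt[[aa]] / tot,
        bg_prop = bg[[aa]] / bg_tot,
        fold = (cnt[[aa]] / tot) / (bg[[aa]] / bg_tot),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_fdr(out$p_value[ok])
  rownames(out) <- NULL
  out
}
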