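# Core PHBR machinery: protein contexts, genotypes, window enumeration and
# harmonic best-rank aggregation.

#' Construct a protein context for a missense mutation
#'
#' A protein context holds the reference and alternate residue of a missense
#' mutation together with up to 14 flanking residues on each side -- enough
#' sequence to enumerate every 8--15-mer peptide window containing the
#' mutated position.
#'
#' @param mutation_id Unique identifier, e.g. `"BRAF_V600E"`.
#' @param gene Gene symbol.
#' @param ref_aa,alt_aa One-letter reference/alternate amino acids; must
#'   differ and belong to [AA_ALPHABET].
#' @param position 1-based protein coordinate of the mutated residue.
#' @param upstream,downstream Amino-acid strings immediately before/after the
#'   mutated position (at most 14 residues each; may be shorter near protein
#'   termini, or empty).
#' @return An object of class `"protein_context"`.
#' @examples
#' ctx <- protein_context("GENE_A5V", "GENE", "A", "V", 5,
#'                        upstream = "MKTW", downstream = "LLGGSPRE")
#' enumerate_windows(ctx, lengths = 8:11)
#' @export
protein_context <- function(mutation_id, gene, ref_aa, alt_aa, position,
                            upstream = "", downstream = "") {
  if (!is_aa_string(ref_aa) || nchar(ref_aa) != 1L)
    stopf("ref_aa must be a single residue in the 20-letter alphabet")
  if (!is_aa_string(alt_aa) || nchar(alt_aa) != 1L)
    stopf("alt_aa must be a single residue in the 20-letter alphabet")
  if (ref_aa == alt_aa)
    stopf("ref_aa and alt_aa must differ (synonymous changes carry no window)")
  if (!is_aa_string(upstream) || !is_aa_string(downstream))
    stopf("flanking sequences may only contain the 20-letter alphabet")
  if (nchar(upstream) > 14L || nchar(downstream) > 14L)
    stopf("flanking sequences are limited to 14 residues each")
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stopf("position must be a positive integer")
  structure(
    list(mutation_id = as.character(mutation_id), gene = as.character(gene),
         ref_aa = ref_aa, alt_aa = alt_aa, position = position,
         upstream = upstream, downstream = downstream),
    class = "protein_context"
  )
}

#' @export
print.protein_context <- function(x, ...) {
  cat(sprintf("<protein_context> %s (%s %s%d%s)\n  ...%s[%s/%s]%s...\n",
              x$mutation_id, x$gene, x$ref_aa, x$position, x$alt_aa,
              x$upstream, x$ref_aa, x$alt_aa, x$downstream))
  invisible(x)
}

#' Validate a table of protein contexts
#'
#' Checks that a data frame carries the protein-context columns
#' (`mutation_id`, `gene`, `ref_aa`, `alt_aa`, `position`, `upstream`,
#' `downstream`), validates every row with [protein_context()] and returns
#' the table with class `"phbr_contexts"` prepended.
#'
#' @param df A data frame of contexts, one mutation per row.
#' @return The validated data frame.
#' @export
as_protein_contexts <- function(df) {
  req <- c("mutation_id", "gene", "ref_aa", "alt_aa", "position",
           "upstream", "downstream")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stopf("context table is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$mutation_id))
    stopf("mutation_id values must be unique")
  for (i in seq_len(nrow(df))) {
    protein_context(df$mutation_id[i], df$gene[i], df$ref_aa[i],
                    df$alt_aa[i], df$position[i],
                    df$upstream[i] %||% "", df$downstream[i] %||% "")
  }
  class(df) <- unique(c("phbr_contexts", class(df)))
  df
}

context_row <- function(contexts, i) {
  protein_context(contexts$mutation_id[i], contexts$gene[i],
                  contexts$ref_aa[i], contexts$alt_aa[i],
                  contexts$position[i], contexts$upstream[i],
                  contexts$downstream[i])
}

#' Construct an MHC genotype
#'
#' @param alleles Character vector of allele names; exactly 6 for MHC class I
#'   (two copies each of HLA-A/B/C) and exactly 10 for class II. Duplicated
#'   entries encode homozygosity and contribute twice to the harmonic mean.
#' @param mhc_class `"I"` or `"II"`.
#' @param id Genotype identifier (defaults to the concatenated allele list).
#' @return An object of class `"mhc_genotype"`.
#' @export
genotype <- function(alleles, mhc_class = c("I", "II"), id = NULL) {
  mhc_class <- match.arg(mhc_class)
  need <- if (mhc_class == "I") 6L else 10L
  alleles <- as.character(alleles)
  if (length(alleles) != need)
    stopf("MHC class %s genotypes carry exactly %d alleles, got %d",
          mhc_class, need, length(alleles))
  structure(
    list(id = id %||% paste(alleles, collapse = "|"),
         mhc_class = mhc_class, alleles = alleles),
    class = "mhc_genotype"
  )
}

#' @export
print.mhc_genotype <- function(x, ...) {
  cat(sprintf("<mhc_genotype class %s> %s\n  %s\n", x$mhc_class, x$id,
              paste(x$alleles, collapse = ", ")))
  invisible(x)
}

#' The prototypical MHC genotype
#'
#' The fixed genotype assigned to isogenotypic virtual patients: the two most
#' common alleles per HLA gene in a Caucasian blood-donor reference
#' population (class I: A02:01, A01:01, B07:02, B08:01, C07:01, C07:02;
#' class II: the corresponding ten DP/DQ/DR subunit alleles).
#'
#' @param mhc_class `"I"` or `"II"`.
#' @return An `"mhc_genotype"`.
#' @export
prototypical_genotype <- function(mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  if (mhc_class == "I") {
    genotype(c("HLA-A02:01", "HLA-A01:01", "HLA-B07:02",
               "HLA-B08:01", "HLA-C07:01", "HLA-C07:02"),
             "I", id = "prototype_I")
  } else {
    genotype(c("HLA-DPA10103", "HLA-DPA10201", "HLA-DPB10201",
               "HLA-DPB10401", "HLA-DQA10102", "HLA-DQA10501",
               "HLA-DQB10301", "HLA-DQB10202", "HLA-DRB10701",
               "HLA-DRB11501"),
             "II", id = "prototype_II")
  }
}

#' Peptide window lengths for an MHC class
#'
#' Class I predictors score 8--11-mers; class II predictors score 15-mers.
#' With full 14/14 flanks these give 38 and 15 mutation-containing windows
#' respectively.
#'
#' @param mhc_class `"I"` or `"II"`.
#' @return Integer vector of window lengths.
#' @export
mhc_window_lengths <- function(mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  if (mhc_class == "I") 8:11 else 15L
}

#' Enumerate mutation-containing peptide windows
#'
#' Lists every substring of `upstream + X + downstream` (where `X` is the
#' alternate residue for mutant peptides, the reference residue for wild-type
#' peptides) that has one of the requested lengths, contains the mutated
#' position, and lies fully within the available flanking sequence. Windows
#' are returned in deterministic order: by increasing length, then
#' left-to-right start position. Duplicate peptide strings are retained.
#'
#' Near protein termini fewer windows fit; if no window of any requested
#' length fits, an empty vector is returned with a warning.
#'
#' @param context A [protein_context()].
#' @param lengths Integer window lengths, each between 8 and 25.
#' @param use_alt Use the alternate (mutant) residue at the mutated position?
#' @return Character vector of peptides.
#' @export
enumerate_windows <- function(context, lengths = 8:11, use_alt = TRUE) {
  stopifnot(inherits(context, "protein_context"))
  lengths <- sort(unique(as.integer(lengths)))
  if (any(is.na(lengths)) || any(lengths < 8L) || any(lengths > 25L))
    stopf("window lengths must lie in 8..25")
  x <- if (use_alt) context$alt_aa else context$ref_aa
  seqn <- paste0(context$upstream, x, context$downstream)
  mpos <- nchar(context$upstream) + 1L
  total <- nchar(seqn)
  out <- character(0)
  for (k in lengths) {
    lo <- max(1L, mpos - k + 1L)
    hi <- min(mpos, total - k + 1L)
    if (hi < lo) next
    starts <- lo:hi
    out <- c(out, substring(seqn, starts, starts + k - 1L))
  }
  if (!length(out))
    warnf("no window of the requested lengths fits context %s",
          context$mutation_id)
  out
}

#' Patient Best Rank: minimum rank over a peptide set for one allele
#'
#' The PBR of a mutation for an allele is the minimum percentile rank over
#' all mutation-containing peptide windows -- the best (strongest) predicted
#' binder. Every (peptide, allele) pair must be present in the rank table;
#' a missing pair signals an incomplete prediction run and raises an error
#' naming the offending peptide and allele.
#'
#' @param peptides Character vector of peptides (duplicates allowed).
#' @param allele Allele name.
#' @param ranks A [rank_table()].
#' @return The minimum rank (numeric scalar).
#' @export
patient_best_rank <- function(peptides, allele, ranks) {
  if (!length(peptides)) stopf("no peptides supplied")
  r <- rank_lookup(ranks, peptides, rep(allele, length(peptides)))
  min(r)
}

#' Harmonic mean of per-allele best ranks (PHBR)
#'
#' Aggregates per-allele PBR scores into the Patient Harmonic Best Rank:
#' `n / sum(1/pbr)`. The harmonic mean is dominated by the smallest (best)
#' rank, so one strongly presenting allele keeps the PHBR low. Homozygous
#' alleles appear twice in the input and contribute two identical terms.
#'
#' @param pbrs Numeric vector of strictly positive PBR scores (length 6 for
#'   class I, 10 for class II in normal use; any positive length accepted).
#' @return The harmonic mean.
#' @export
harmonic_phbr <- function(pbrs) {
  if (!length(pbrs)) stopf("empty PBR vector")
  if (any(!is.finite(pbrs)) || any(pbrs <= 0))
    stopf("all PBR scores must be positive and finite (rank floor is 0.001)")
  length(pbrs) / sum(1 / pbrs)
}

#' Score one mutation against one genotype
#'
#' Composes [enumerate_windows()], [patient_best_rank()] per genotype allele
#' slot, and [harmonic_phbr()], for both the mutant and the wild-type peptide
#' set, and reports the difference `delta_phbr = phbr - phbr_wt` (positive
#' values mean the substitution weakens presentation).
#'
#' @param context A [protein_context()].
#' @param genotype An [genotype()] object.
#' @param ranks_mut,ranks_wt [rank_table()]s covering all mutant (wild-type)
#'   windows for every genotype allele. `ranks_wt` defaults to `ranks_mut`
#'   when a single table covers both peptide sets.
#' @param lengths Window lengths; defaults to the class-appropriate set.
#' @return An object of class `"phbr_score"`: a list with `mutation_id`,
#'   `genotype_id`, `pbr_per_allele`, `pbr_per_allele_wt`, `phbr`, `phbr_wt`,
#'   `delta_phbr` and `n_windows`.
#' @export
score_mutation <- function(context, genotype, ranks_mut, ranks_wt = ranks_mut,
                           lengths = NULL) {
  stopifnot(inherits(genotype, "mhc_genotype"))
  lengths <- lengths %||% mhc_window_lengths(genotype$mhc_class)
  win_mut <- enumerate_windows(context, lengths, use_alt = TRUE)
  win_wt <- enumerate_windows(context, lengths, use_alt = FALSE)
  pbr_mut <- vapply(genotype$alleles, function(a)
    patient_best_rank(win_mut, a, ranks_mut), numeric(1))
  pbr_wt <- vapply(genotype$alleles, function(a)
    patient_best_rank(win_wt, a, ranks_wt), numeric(1))
  phbr <- harmonic_phbr(pbr_mut)
  phbr_wt <- harmonic_phbr(pbr_wt)
  structure(
    list(mutation_id = context$mutation_id, genotype_id = genotype$id,
         pbr_per_allele = pbr_mut, pbr_per_allele_wt = pbr_wt,
         phbr = phbr, phbr_wt = phbr_wt, delta_phbr = phbr - phbr_wt,
         n_windows = length(win_mut)),
    class = "phbr_score"
  )
}

#' @export
print.phbr_score <- function(x, ...) {
  cat(sprintf(
    "<phbr_score> %s vs %s\n  PHBR %.4f  PHBR_wt %.4f  dPHBR %+.4f  (%d windows)\n",
    x$mutation_id, x$genotype_id, x$phbr, x$phbr_wt, x$delta_phbr,
    x$n_windows))
  invisible(x)
}
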