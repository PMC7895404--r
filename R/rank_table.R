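# Rank tables: the contract boundary between PHBR scoring and any affinity
# predictor (external or synthetic).

RANK_FLOOR <- 0.001
RANK_CEIL <- 100

#' Normalize HLA allele names
#'
#' Applies the package's versioned normalization rules (v1): strip `*`
#' separators and whitespace, so `"HLA-A*02:01"` and `"HLA-A 02:01"` both
#' become `"HLA-A02:01"`. Case and the `HLA-` prefix are preserved as given;
#' rank tables and genotypes must agree on them.
#'
#' @param alleles Character vector of allele names.
#' @return Normalized character vector.
#' @export
normalize_allele <- function(alleles) {
  gsub("[*[:space:]]", "", as.character(alleles))
}

#' Build a peptide-by-allele percentile rank table
#'
#' Stores predictor output as a mapping `(peptide, allele) -> rank`, with
#' rank the percentile of predicted binding strength (lower = stronger
#' binder). Ranks are clamped to `[0.001, 100]`: external predictors report
#' 0.001 as their minimum and unclamped zeros would blow up the harmonic
#' mean. Exact duplicate rows are collapsed; duplicated pairs with differing
#' ranks are ambiguous and rejected.
#'
#' @param peptide,allele,rank Parallel vectors defining the entries.
#' @return An object of class `"rank_table"` (a keyed `data.table`).
#' @export
rank_table <- function(peptide, allele, rank) {
  stopifnot(length(peptide) == length(allele),
            length(peptide) == length(rank))
  rank <- as.numeric(rank)
  if (any(is.na(rank))) stopf("ranks must be numeric and non-missing")
  if (any(rank <= 0 | rank > RANK_CEIL))
    warnf("%d rank(s) outside (0, 100] clamped to [%.3g, %g]",
          sum(rank <= 0 | rank > RANK_CEIL), RANK_FLOOR, RANK_CEIL)
  rank <- pmin(pmax(rank, RANK_FLOOR), RANK_CEIL)
  dt <- data.table::data.table(
    peptide = as.character(peptide),
    allele = normalize_allele(allele),
    rank = rank
  )
  dt <- unique(dt)
  dup <- duplicated(dt, by = c("peptide", "allele"))
  if (any(dup)) {
    bad <- dt[dup][1L]
    stopf("conflicting ranks for peptide %s / allele %s",
          bad$peptide, bad$allele)
  }
  data.table::setkeyv(dt, c("peptide", "allele"))
  class(dt) <- unique(c("rank_table", class(dt)))
  dt
}

# Vectorized lookup; errors on the first missing (peptide, allele) pair.
rank_lookup <- function(ranks, peptides, alleles) {
  stopifnot(inherits(ranks, "rank_table"))
  q <- data.table::data.table(peptide = peptides,
                              allele = normalize_allele(alleles))
  res <- ranks[q, on = c("peptide", "allele")]
  miss <- which(is.na(res$rank))
  if (length(miss)) {
    stopf("no rank for peptide %s / allele %s (incomplete prediction run?)",
          q$peptide[miss[1L]], q$allele[miss[1L]])
  }
  res$rank
}

#' Parse a rank table from predictor output
#'
#' Two dialects are supported. `"long_tsv"` is the canonical interchange
#' format: a tab-separated file with header columns `peptide`, `allele`,
#' `rank` (case-insensitive, any column order). `"netmhcpan_xls"` is a
#' narrow convenience adapter for the tab-separated `-xls` export of
#' NetMHCpan-style predictors: line 1 names the alleles above their column
#' blocks, line 2 names per-block columns, and each block's `Rank`
#' (or `EL_Rank`) column is extracted together with the `Peptide` column.
#'
#' Ranks outside `(0, 100]` are clamped to `[0.001, 100]` with a warning;
#' rows that fail to parse raise an error with their line number.
#'
#' @param path Path to the file.
#' @param dialect `"long_tsv"` or `"netmhcpan_xls"`.
#' @return A [rank_table()].
#' @export
parse_rank_table <- function(path, dialect = c("long_tsv", "netmhcpan_xls")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (dialect == "long_tsv") parse_rank_long_tsv(path) else
    parse_rank_netmhcpan_xls(path)
}

parse_rank_long_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2))
  names(dt) <- tolower(names(dt))
  req <- c("peptide", "allele", "rank")
  if (!all(req %in% names(dt)))
    stopf("long_tsv rank file needs columns peptide/allele/rank, found: %s",
          paste(names(dt), collapse = ", "))
  rk <- suppressWarnings(as.numeric(dt$rank))
  bad <- which(is.na(rk))
  if (length(bad))
    stopf("unparseable rank on line %d of %s", bad[1L] + 1L, path)
  rank_table(dt$peptide, dt$allele, rk)
}

parse_rank_netmhcpan_xls <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stopf("truncated netmhcpan_xls file: %s", path)
  hdr1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  hdr2 <- strsplit(lines[2L], "\t", fixed = TRUE)[[1]]
  allele_at <- which(nzchar(trimws(hdr1)))
  alleles <- trimws(hdr1[allele_at])
  if (!length(alleles)) stopf("no allele names on line 1 of %s", path)
  pep_col <- which(tolower(trimws(hdr2)) == "peptide")[1]
  if (is.na(pep_col)) stopf("no Peptide column on line 2 of %s", path)
  out <- list()
  for (i in seq_along(alleles)) {
    # rank column: first Rank/EL_Rank header at or after the allele anchor
    cand <- which(tolower(trimws(hdr2)) %in% c("rank", "el_rank", "rank_el"))
    cand <- cand[cand >= allele_at[i]]
    if (i < length(alleles)) cand <- cand[cand < allele_at[i + 1L]]
    if (!length(cand))
      stopf("no Rank column for allele %s in %s", alleles[i], path)
    rank_col <- cand[1L]
    for (ln in seq(3L, length(lines))) {
      f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
      if (length(f) < rank_col || !nzchar(trimws(lines[ln]))) next
      rk <- suppressWarnings(as.numeric(f[rank_col]))
      if (is.na(rk)) stopf("unparseable rank on line %d of %s", ln, path)
      out[[length(out) + 1L]] <- list(peptide = f[pep_col],
                                      allele = alleles[i], rank = rk)
    }
  }
  dt <- data.table::rbindlist(out)
  rank_table(dt$peptide, dt$allele, dt$rank)
}

#' Write a rank table in the canonical long TSV format
#'
#' @param ranks A [rank_table()].
#' @param path Output path.
#' @export
write_rank_table <- function(ranks, path) {
  stopifnot(inherits(ranks, "rank_table"))
  data.table::fwrite(ranks, path, sep = "\t")
  invisible(path)
}
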