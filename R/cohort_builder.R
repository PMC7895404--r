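# From somatic mutation calls to the binary patient x mutation matrix.

#' Read MAF-style somatic mutation calls
#'
#' Reads a tab-delimited mutation annotation file and extracts the four
#' columns this package uses: gene symbol, variant classification, protein
#' change and sample barcode. Column names are configurable; the defaults
#' match MC3-style MAFs.
#'
#' @param path Path to the tab-delimited file.
#' @param col_gene,col_class,col_protein,col_sample Source column names.
#' @return A data frame with columns `gene`, `variant_classification`,
#'   `protein_change`, `sample_id`.
#' @export
read_maf <- function(path, col_gene = "Hugo_Symbol",
                     col_class = "Variant_Classification",
                     col_protein = "HGVSp_Short",
                     col_sample = "Tumor_Sample_Barcode") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  req <- c(col_gene, col_class, col_protein, col_sample)
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols))
    stopf("MAF is missing columns: %s", paste(missing_cols, collapse = ", "))
  data.frame(gene = dt[[col_gene]],
             variant_classification = dt[[col_class]],
             protein_change = dt[[col_protein]],
             sample_id = dt[[col_sample]],
             stringsAsFactors = FALSE)
}

#' Parse protein-change notation
#'
#' Accepts the `"p.V600E"` and bare `"V600E"` dialects of single-residue
#' missense notation. Anything else (frameshifts, stops, multi-residue
#' changes) returns `NA` fields.
#'
#' @param x Character vector of protein-change strings.
#' @return Data frame with columns `ref_aa`, `position`, `alt_aa` (NA where
#'   unparseable).
#' @export
parse_protein_change <- function(x) {
  m <- regmatches(x, regexec("^(?:p\\.)?([A-Z])([0-9]+)([A-Z])$", x))
  ref <- vapply(m, function(g) if (length(g) == 4L) g[2L] else NA_character_, "")
  pos <- vapply(m, function(g) if (length(g) == 4L) g[3L] else NA_character_, "")
  alt <- vapply(m, function(g) if (length(g) == 4L) g[4L] else NA_character_, "")
  ok <- !is.na(ref) & ref %in% AA_ALPHABET & alt %in% AA_ALPHABET
  ref[!ok] <- NA_character_; alt[!ok] <- NA_character_; pos[!ok] <- NA_character_
  data.frame(ref_aa = ref, position = as.integer(pos), alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Filter somatic calls to recurrent driver missense mutations
#'
#' Applies the three driver-mutation filters: (1) missense variant
#' classification, (2) gene in the supplied driver list, (3) observed in at
#' least `min_recurrence` distinct samples. Recurrence counts distinct
#' samples, not raw rows, so duplicated calls within one sample count once.
#' Missense rows whose protein change fails to parse are dropped with a
#' warning.
#'
#' @param records Data frame from [read_maf()] (columns `gene`,
#'   `variant_classification`, `protein_change`, `sample_id`).
#' @param gene_list Character vector of driver gene symbols.
#' @param min_recurrence Minimum number of distinct carrier samples
#'   (default 5).
#' @param missense_labels Variant-classification values treated as missense
#'   (matched case-insensitively).
#' @return Character vector of mutation ids (`"GENE_V600E"`), ordered by
#'   decreasing recurrence then id.
#' @export
filter_driver_mutations <- function(records, gene_list, min_recurrence = 5L,
                                    missense_labels = c("Missense_Mutation")) {
  stopifnot(min_recurrence >= 1L)
  is_mis <- tolower(records$variant_classification) %in%
    tolower(missense_labels)
  rec <- records[is_mis & records$gene %in% gene_list, , drop = FALSE]
  if (!nrow(rec)) return(character(0))
  pc <- parse_protein_change(rec$protein_change)
  bad <- is.na(pc$ref_aa)
  if (any(bad)) {
    warnf("dropping %d missense row(s) with unparseable protein change (e.g. %s)",
          sum(bad), rec$protein_change[which(bad)[1L]])
    rec <- rec[!bad, , drop = FALSE]
    pc <- pc[!bad, , drop = FALSE]
  }
  if (!nrow(rec)) return(character(0))
  mid <- paste0(rec$gene, "_", pc$ref_aa, pc$position, pc$alt_aa)
  counts <- tapply(rec$sample_id, mid, function(s) length(unique(s)))
  keep <- counts[counts >= min_recurrence]
  names(keep)[order(-keep, names(keep))]
}

#' Mutation-matrix container
#'
#' Wraps a binary patients x mutations incidence matrix and derives the
#' per-mutation carrier frequencies (column sums divided by the number of
#' patients).
#'
#' @param incidence Binary integer matrix, patients in rows, mutations in
#'   columns, with dimnames.
#' @return An object of class `"mutation_matrix"` with elements `incidence`,
#'   `patients`, `mutations`, `frequencies`.
#' @export
mutation_matrix <- function(incidence) {
  if (!is.matrix(incidence) || !all(incidence %in% c(0L, 1L)))
    stopf("incidence must be a binary matrix")
  storage.mode(incidence) <- "integer"
  if (is.null(rownames(incidence)))
    rownames(incidence) <- sprintf("P%05d", seq_len(nrow(incidence)))
  if (is.null(colnames(incidence)))
    colnames(incidence) <- sprintf("M%04d", seq_len(ncol(incidence)))
  structure(
    list(incidence = incidence,
         patients = rownames(incidence),
         mutations = colnames(incidence),
         frequencies = colSums(incidence) / nrow(incidence)),
    class = "mutation_matrix"
  )
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("<mutation_matrix> %d patients x %d mutations, %d events\n",
              length(x$patients), length(x$mutations), sum(x$incidence)))
  invisible(x)
}

#' Build the binary patient x mutation incidence matrix
#'
#' Cell (p, m) is 1 iff any record maps sample p to mutation m. Patients
#' without any retained mutation keep all-zero rows; duplicate records are
#' idempotent.
#'
#' @param records Data frame as in [filter_driver_mutations()].
#' @param mutation_ids Mutations (columns) to include.
#' @param patient_ids Patients (rows); defaults to the sorted distinct
#'   sample ids in `records`.
#' @return A [mutation_matrix()].
#' @export
build_mutation_matrix <- function(records, mutation_ids, patient_ids = NULL) {
  if (!length(mutation_ids)) stopf("mutation_ids must be non-empty")
  patient_ids <- patient_ids %||% sort(unique(records$sample_id))
  inc <- matrix(0L, nrow = length(patient_ids), ncol = length(mutation_ids),
                dimnames = list(patient_ids, mutation_ids))
  if (nrow(records)) {
    pc <- parse_protein_change(records$protein_change)
    mid <- paste0(records$gene, "_", pc$ref_aa, pc$position, pc$alt_aa)
    sel <- !is.na(pc$ref_aa) & mid %in% mutation_ids &
      records$sample_id %in% patient_ids
    if (any(sel)) {
      inc[cbind(match(records$sample_id[sel], patient_ids),
                match(mid[sel], mutation_ids))] <- 1L
    }
  }
  mutation_matrix(inc)
}

#' Share of mutation events carried by the k most frequent mutations
#'
#' Counts the mutation events (matrix cell sum) attributable to the `k` most
#' frequent mutations. Ties in frequency are broken by the matrix's mutation
#' order. The percentage is rounded to one decimal.
#'
#' @param matrix A [mutation_matrix()].
#' @param k Number of top mutations.
#' @return List with `count_top_k`, `count_total` and `percent`.
#' @export
top_k_share <- function(matrix, k) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  counts <- colSums(matrix$incidence)
  if (!length(counts) || sum(counts) == 0)
    stopf("empty mutation matrix")
  if (k > length(counts)) stopf("k exceeds the number of mutations")
  ord <- order(-counts, seq_along(counts))
  top <- sum(counts[ord[seq_len(k)]])
  total <- sum(counts)
  list(count_top_k = as.integer(top), count_total = as.integer(total),
       percent = round(100 * top / total, 1))
}

#' Read a driver gene list (one symbol per line)
#'
#' @param path Path to a text file with one gene symbol per line.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
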