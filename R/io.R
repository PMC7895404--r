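# Plain-text IO helpers for the pipeline's interchange formats.

#' Read a protein-context table from TSV
#'
#' Expects the canonical columns `mutation_id`, `gene`, `ref_aa`, `alt_aa`,
#' `position`, `upstream`, `downstream`.
#'
#' @param path Path to a tab-separated file.
#' @return A validated context table (class `"phbr_contexts"`).
#' @export
read_contexts <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  dt$position <- as.integer(dt$position)
  as_protein_contexts(as.data.frame(dt))
}

#' Write a protein-context table as TSV
#'
#' @param contexts A context table.
#' @param path Output path.
#' @export
write_contexts <- function(contexts, path) {
  contexts <- as_protein_contexts(contexts)
  data.table::fwrite(contexts, path, sep = "\t")
  invisible(path)
}

#' Read genotypes from a JSON config
#'
#' Accepts either a single genotype object
#' (`{"id": ..., "mhc_class": "I", "alleles": [...]}`) or an array of them.
#'
#' @param path Path to the JSON file.
#' @return A list of `"mhc_genotype"` objects.
#' @export
read_genotypes_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stopf("reading genotype JSON requires the jsonlite package")
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.null(x$alleles)) x <- list(x)
  lapply(x, function(g)
    genotype(unlist(g$alleles), g$mhc_class %||% "I", id = g$id))
}

#' Read a binary mutation matrix from TSV
#'
#' Expects a `patient_id` column followed by one binary column per mutation,
#' as written by [write_scenario()].
#'
#' @param path Path to the TSV file.
#' @return A [mutation_matrix()].
#' @export
read_mutation_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"patient_id" %in% names(dt))
    stopf("mutation matrix TSV needs a patient_id column")
  inc <- as.matrix(dt[, !"patient_id"])
  rownames(inc) <- dt$patient_id
  mutation_matrix(inc)
}

#' Write a leave-one-out scan as TSV
#'
#' @param loo A `"phbr_loo"` object.
#' @param path Output path.
#' @export
write_loo <- function(loo, path) {
  stopifnot(inherits(loo, "phbr_loo"))
  data.table::fwrite(as.data.frame(loo), path, sep = "\t")
  invisible(path)
}
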