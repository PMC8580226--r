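# Apply the calibrated model collection to proteomes and metagenome gene
# catalogs, aggregate hits to module level, and apply the two normalizations
# used for the heatmap-style summaries: per-sample relative abundance and
# per-module division by the maximum sample.

.check_models_calibrated <- function(models) {
  no_ga <- vapply(models, function(h) is.null(h$ga_bits), TRUE)
  if (any(no_ga))
    stop("model(s) without GA threshold: ",
         paste(vapply(models[no_ga], `[[`, "", "name"), collapse = ", "))
}

#' Scan one proteome with a calibrated model collection
#'
#' Counts, per model, the proteins scoring at or above the model's GA. A
#' protein may count toward several models (per-model thresholding, matching
#' independent per-model searches).
#'
#' @param models list of calibrated `profile_hmm`
#' @param proteins protein record data frame (one proteome); may be empty
#' @param row_id row label; defaults to the proteome's genome id
#' @return 1-row [labeled_matrix()] of counts (`raw_counts`)
#' @export
scan_proteome <- function(models, proteins, row_id = NULL) {
  .check_models_calibrated(models)
  nm <- vapply(models, `[[`, "", "name")
  if (is.null(row_id))
    row_id <- if (nrow(proteins)) unique(proteins$genome_id)[1] else "proteome"
  if (nrow(proteins) == 0)
    return(labeled_matrix(matrix(0, 1, length(nm)), row_id, nm))
  bits <- score_matrix(models, proteins)
  ga <- vapply(models, `[[`, 0.0, "ga_bits")
  counts <- colSums(bits >= rep(ga, each = nrow(bits)))
  labeled_matrix(matrix(counts, 1), row_id, nm)
}

#' Scan a panel of genomes
#'
#' @param models list of calibrated `profile_hmm`
#' @param proteins protein record data frame covering several genomes
#' @return [labeled_matrix()] genomes x models of counts
#' @export
scan_genomes <- function(models, proteins) {
  .check_models_calibrated(models)
  nm <- vapply(models, `[[`, "", "name")
  ga <- vapply(models, `[[`, 0.0, "ga_bits")
  bits <- score_matrix(models, proteins)
  pass <- bits >= rep(ga, each = nrow(bits))
  gsplit <- split(seq_len(nrow(proteins)), proteins$genome_id)
  counts <- t(vapply(gsplit, function(ix)
    colSums(pass[ix, , drop = FALSE]), numeric(length(nm))))
  labeled_matrix(counts, names(gsplit), nm)
}

#' Quantify models in a metagenome gene catalog
#'
#' Each catalog gene is assigned to every model whose GA it passes; the
#' model's per-sample value is the sum of read counts of its genes. A gene
#' passing two models contributes its counts to both. Genes hit by no model
#' are accounted in an `UNMAPPED` column.
#'
#' @param models list of calibrated `profile_hmm`
#' @param gene_catalog protein record data frame of called genes
#' @param gene_counts [labeled_matrix()] samples x genes of read counts
#' @return [labeled_matrix()] samples x (models + UNMAPPED), `raw_counts`
#' @export
quantify_metagenome <- function(models, gene_catalog, gene_counts) {
  .check_models_calibrated(models)
  missing <- setdiff(colnames(gene_counts), gene_catalog$protein_id)
  if (length(missing))
    stop("gene(s) missing from catalog: ", paste(missing, collapse = ", "))
  genes <- gene_catalog[match(colnames(gene_counts), gene_catalog$protein_id), ]
  bits <- score_matrix(models, genes)
  ga <- vapply(models, `[[`, 0.0, "ga_bits")
  pass <- bits >= rep(ga, each = nrow(bits))   # genes x models
  vals <- unclass(gene_counts) %*% pass
  unmapped <- rowSums(unclass(gene_counts)[, rowSums(pass) == 0, drop = FALSE])
  labeled_matrix(cbind(vals, UNMAPPED = unmapped),
                 rownames(gene_counts), c(colnames(pass), "UNMAPPED"))
}

# shared column-group summation; keeps any extra columns listed in `extra`
.aggregate_columns <- function(hits, groups, extra = "UNMAPPED") {
  want <- unlist(groups, use.names = FALSE)
  absent <- setdiff(want, colnames(hits))
  if (length(absent)) {
    warning("model column(s) absent, zero-filled: ",
            paste(absent, collapse = ", "))
    hits <- labeled_matrix(
      cbind(unclass(hits), matrix(0, nrow(hits), length(absent))),
      rownames(hits), c(colnames(hits), absent), norm_state(hits))
  }
  agg <- vapply(groups, function(cols)
    rowSums(unclass(hits)[, cols, drop = FALSE]), numeric(nrow(hits)))
  if (nrow(hits) == 1L) agg <- matrix(agg, nrow = 1L)
  keep <- intersect(extra, colnames(hits))
  out <- cbind(agg, unclass(hits)[, keep, drop = FALSE])
  labeled_matrix(out, rownames(hits), c(names(groups), keep),
                 norm_state(hits))
}

#' Aggregate model-level hits to module level
#'
#' Module columns are the row-wise sums of their member model columns; with
#' a catalog covering every model, row totals are conserved. Models listed in
#' the catalog but absent from the table are zero-filled with a warning. An
#' `UNMAPPED` column, if present, is carried through unchanged.
#'
#' @param hits [labeled_matrix()] rows x models
#' @param catalog a `module_catalog`
#' @param by aggregate by `"module_id"` (default) or `"pathway"`
#' @return [labeled_matrix()] rows x modules
#' @export
aggregate_modules <- function(hits, catalog, by = c("module_id", "pathway")) {
  by <- match.arg(by)
  .aggregate_columns(hits, module_members(catalog, by))
}

#' Per-sample relative abundance
#'
#' Divides each row by its row sum so differences in sequencing depth between
#' samples drop out. Zero-sum rows are left as zeros with a warning. An
#' `UNMAPPED` column is excluded from the denominator by default (so the
#' functional columns sum to 1) but is scaled by the same factor.
#'
#' @param hits [labeled_matrix()] with `norm_state = "raw_counts"`
#' @param include_unmapped include the `UNMAPPED` column in the denominator
#' @return [labeled_matrix()] with `norm_state = "sample_relative"`
#' @export
renorm_sample_relative <- function(hits, include_unmapped = FALSE) {
  if (norm_state(hits) != "raw_counts")
    stop("renorm_sample_relative expects raw counts, got ", norm_state(hits))
  vals <- unclass(hits)
  denom_cols <- colnames(vals)
  if (!include_unmapped) denom_cols <- setdiff(denom_cols, "UNMAPPED")
  rs <- rowSums(vals[, denom_cols, drop = FALSE])
  if (any(rs == 0)) warning("zero-sum row(s) left as zeros: ",
                            paste(rownames(vals)[rs == 0], collapse = ", "))
  scale <- ifelse(rs > 0, 1 / rs, 0)
  out <- vals * scale
  .set_norm_state(labeled_matrix(out, rownames(hits), colnames(hits),
                                 "raw_counts"), "sample_relative")
}

#' Per-module maximum normalization
#'
#' Divides every module column by its maximum over the full combined sample
#' set (all cohorts jointly), so all samples within one module are relative
#' to each other, between 0 and 1. All-zero columns are preserved.
#' Idempotent.
#'
#' @param hits module-level [labeled_matrix()], `sample_relative` (or already
#'   `module_max`)
#' @return [labeled_matrix()] with `norm_state = "module_max"`
#' @export
normalize_module_max <- function(hits) {
  if (!norm_state(hits) %in% c("sample_relative", "module_max"))
    stop("normalize_module_max expects sample_relative input, got ",
         norm_state(hits))
  vals <- unclass(hits)
  mx <- apply(vals, 2, max)
  out <- sweep(vals, 2, ifelse(mx > 0, mx, 1), "/")
  .set_norm_state(labeled_matrix(out, rownames(hits), colnames(hits),
                                 "raw_counts"), "module_max")
}
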