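# Functional-potential inference from 16S compositions: OTUs are mapped to
# reference-panel genomes by deepest-matching taxonomic prefix and the
# genomes' gene (model) counts are projected through the OTU abundances,
# in the spirit of PICRUSt.

#' Bundle an OTU table with its taxonomy
#'
#' @param counts [labeled_matrix()] samples x OTUs (non-negative counts)
#' @param taxonomy named character vector, one rank-delimited (`;`) taxonomy
#'   string per OTU (possibly `"Unassigned"`)
#' @return an `otu_data` object
#' @export
otu_data <- function(counts, taxonomy) {
  stopifnot(inherits(counts, "labeled_matrix"))
  miss <- setdiff(colnames(counts), names(taxonomy))
  if (length(miss))
    stop("OTU(s) without taxonomy entry: ", paste(miss, collapse = ", "))
  structure(list(counts = counts,
                 taxonomy = taxonomy[colnames(counts)]),
            class = "otu_data")
}

.split_taxonomy <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  # tolerate greengenes-style rank prefixes ("g__Staphylococcus")
  parts <- sub("^[a-z]__", "", parts)
  parts[nzchar(parts)]
}

#' Map OTUs to reference-panel genomes by taxonomy
#'
#' Each OTU is assigned to the panel genome(s) with the deepest matching
#' taxonomic prefix; ties are recorded as equal weights over the tied
#' genomes. OTUs whose match is shallower than `min_depth` ranks (default 6,
#' the genus rank in the seven-rank convention), or labeled `"Unassigned"`,
#' are unmapped.
#'
#' @param otus an [otu_data()]
#' @param panel_taxa named character vector: genome id -> taxonomy string
#' @param min_depth minimum shared prefix depth for a mapping
#' @return data frame of class `genome_map`: `otu_id`, `genome_id` (NA if
#'   unmapped), `weight`, `depth`, `method` (`exact_taxon`/`nearest_rank`)
#' @export
map_otus_to_genomes <- function(otus, panel_taxa, min_depth = 6) {
  ptax <- lapply(panel_taxa, .split_taxonomy)
  rows <- lapply(colnames(otus$counts), function(otu) {
    s <- otus$taxonomy[[otu]]
    if (is.na(s) || !nzchar(s))
      stop("malformed taxonomy for OTU ", otu)
    unmapped <- data.frame(otu_id = otu, genome_id = NA_character_,
                           weight = 0, depth = 0L,
                           method = NA_character_, stringsAsFactors = FALSE)
    if (identical(s, "Unassigned")) return(unmapped)
    ot <- .split_taxonomy(s)
    if (!length(ot)) stop("malformed taxonomy for OTU ", otu)
    depth <- vapply(ptax, function(p) {
      n <- min(length(p), length(ot))
      same <- p[seq_len(n)] == ot[seq_len(n)]
      if (all(same)) n else (which(!same)[1] - 1L)
    }, 0L)
    d <- max(depth)
    if (d < min_depth) return(unmapped)
    hit <- names(depth)[depth == d]
    exact <- length(hit) == 1L && d == length(ot) &&
      length(ptax[[hit[1]]]) == length(ot)
    data.frame(otu_id = otu, genome_id = hit, weight = 1 / length(hit),
               depth = d,
               method = if (exact) "exact_taxon" else "nearest_rank",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("genome_map", "data.frame")
  out
}

#' Fraction of unmapped OTU abundance per sample
#' @param otus an [otu_data()]
#' @param mapping a `genome_map`
#' @return named numeric vector (per sample)
#' @export
unmapped_fraction <- function(otus, mapping) {
  un <- mapping$otu_id[is.na(mapping$genome_id)]
  vals <- unclass(otus$counts)
  tot <- rowSums(vals)
  frac <- rowSums(vals[, un, drop = FALSE]) / ifelse(tot > 0, tot, 1)
  setNames(frac, rownames(vals))
}

#' Predict per-sample gene (model) content from an OTU table
#'
#' `predicted(sample, model) = sum over OTUs of abundance(sample, OTU) x
#' sum over mapped genomes of weight x count(genome, model)` — exactly
#' linear in the OTU abundances. Callers wanting compositional output pass
#' sample-relative abundances in (the pipeline does so by default). An
#' optional per-genome 16S copy-number table divides each genome's
#' contribution (PICRUSt-style correction; off by default).
#'
#' @param otus an [otu_data()]
#' @param gene_counts [labeled_matrix()] genomes x models, raw counts
#' @param mapping a `genome_map` from [map_otus_to_genomes()]
#' @param copy_number optional named numeric: genome id -> 16S copy number
#' @return [labeled_matrix()] samples x models
#' @export
predict_gene_content <- function(otus, gene_counts, mapping,
                                 copy_number = NULL) {
  mapped <- mapping[!is.na(mapping$genome_id), , drop = FALSE]
  miss <- setdiff(unique(mapped$genome_id), rownames(gene_counts))
  if (length(miss))
    stop("gene_counts missing genome(s): ", paste(miss, collapse = ", "))
  A <- unclass(otus$counts)                      # samples x OTUs
  W <- matrix(0, ncol(A), nrow(gene_counts),
              dimnames = list(colnames(A), rownames(gene_counts)))
  if (nrow(mapped)) {
    w <- mapped$weight
    if (!is.null(copy_number))
      w <- w / copy_number[mapped$genome_id]
    W[cbind(mapped$otu_id, mapped$genome_id)] <- w
  }
  P <- A %*% W %*% unclass(gene_counts)
  zero <- rowSums(A %*% W) == 0 & rowSums(A) > 0
  if (any(zero))
    warning("sample(s) with only unmapped OTUs: ",
            paste(rownames(A)[zero], collapse = ", "))
  labeled_matrix(P, rownames(A), colnames(gene_counts))
}
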