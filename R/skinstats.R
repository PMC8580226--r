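# Phenotype-side statistics: the skin-aging (SA) score aggregating eight
# clinical measurements, redundancy analysis (RDA) with permutation tests at
# OTU and predicted-gene level, per-pathway linear models against the SA
# score, and the row-max normalized pathway table for heatmap-style export.

#' The eight clinical measurements behind the SA score
#' @export
PHENO_MEASUREMENTS <- c("pores_number", "roughness", "wrinkles_number",
                        "porphyrins_number", "red_features_number",
                        "skin_color_evenness", "spots_visible_number",
                        "spots_invisible_number")

#' Default per-measurement orientation
#'
#' `+1` when a larger value is associated with older-looking skin; skin color
#' evenness decreases with aging and is oriented `-1`.
#' @export
DEFAULT_ORIENTATION <- setNames(c(1, 1, 1, 1, 1, -1, 1, 1), PHENO_MEASUREMENTS)

#' Compute the skin-aging (SA) score
#'
#' Oriented z-score mean over the eight clinical measurements: each column is
#' standardized, multiplied by its orientation, and averaged per subject, so
#' a high SA score means a high score on the parameters associated with an
#' aging skin. Zero-variance columns are dropped with a warning; subjects
#' with missing values are dropped with a warning.
#'
#' @param pheno data frame or matrix, subjects (rows, named) x the eight
#'   measurements
#' @param orientation named `+1`/`-1` vector per column (defaults to
#'   [DEFAULT_ORIENTATION])
#' @return named numeric vector of SA scores (mean approximately 0)
#' @export
compute_sa_score <- function(pheno, orientation = DEFAULT_ORIENTATION) {
  m <- as.matrix(pheno)
  miss <- setdiff(PHENO_MEASUREMENTS, colnames(m))
  if (length(miss))
    stop("phenotype table missing measurement(s): ", paste(miss, collapse = ", "))
  m <- m[, PHENO_MEASUREMENTS, drop = FALSE]
  ok <- stats::complete.cases(m)
  if (!all(ok)) {
    warning("dropping subject(s) with missing values: ",
            paste(rownames(m)[!ok], collapse = ", "))
    m <- m[ok, , drop = FALSE]
  }
  if (nrow(m) < 3) stop("need at least 3 subjects")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) == 0)  # all measurements constant: no variation to aggregate
    return(setNames(rep(0, nrow(m)), rownames(m)))
  z <- scale(m)
  z <- sweep(z, 2, orientation[colnames(m)], "*")
  setNames(rowMeans(z), rownames(m))
}

.hellinger <- function(x) {
  rs <- rowSums(x)
  sqrt(sweep(x, 1, ifelse(rs > 0, rs, 1), "/"))
}

#' Redundancy analysis (RDA) against a single constraint
#'
#' The response (samples x features) is transformed (Hellinger by default),
#' column-centered, and projected onto the centered constraint. Variance
#' explained is the fitted sum of squares over the total; the pseudo-F is
#' `(SS_fit / q) / (SS_res / (n - q - 1))` with `q = 1`, and the permutation
#' p-value is `(1 + #{permuted F >= observed}) / (1 + n_perm)` under random
#' permutation of the constraint across samples.
#'
#' @param response [labeled_matrix()] or numeric matrix, samples x features
#' @param constraint per-sample numeric vector (SA score, or a 0/1 group
#'   indicator), non-constant, aligned with the response rows
#' @param transform `"hellinger"` (default), `"log1p"` or `"none"`
#' @param n_perm number of permutations (default 999)
#' @param seed RNG seed for the permutations (required, for reproducibility)
#' @return an `rda_result`: `var_explained`, `pseudo_F`, `perm_p`,
#'   `site_scores`, `arrow_scores`, `n_perm`, `seed`, `transform`
#' @export
rda <- function(response, constraint,
                transform = c("hellinger", "log1p", "none"),
                n_perm = 999, seed = 1) {
  transform <- match.arg(transform)
  Y <- unclass(as.matrix(response))
  n <- nrow(Y)
  if (n < 4) stop("need at least 4 samples")
  if (length(constraint) != n) stop("constraint length must match samples")
  if (sd(constraint) == 0) stop("constraint is constant")
  if (n_perm < 1) stop("n_perm must be >= 1")
  Yt <- switch(transform, hellinger = .hellinger(Y), log1p = log1p(Y),
               none = Y)
  Yc <- scale(Yt, center = TRUE, scale = FALSE)
  sst <- sum(Yc^2)
  xc <- constraint - mean(constraint)
  fstat <- function(xc) {
    b <- drop(crossprod(Yc, xc)) / sum(xc^2)
    ssf <- sum(xc^2) * sum(b^2)
    list(ssf = ssf, f = (ssf / 1) / ((sst - ssf) / (n - 2)), b = b)
  }
  obs <- fstat(xc)
  set.seed(seed)
  perm_f <- vapply(seq_len(n_perm), function(i) fstat(sample(xc))$f, 0.0)
  b <- obs$b
  bn <- sqrt(sum(b^2))
  structure(list(
    var_explained = obs$ssf / sst,
    pseudo_F = obs$f,
    perm_p = (1 + sum(perm_f >= obs$f)) / (1 + n_perm),
    site_scores = setNames(xc * bn, rownames(Y)),
    arrow_scores = setNames(b, colnames(Y)),
    n_perm = n_perm, seed = seed, transform = transform),
    class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "rda_result: var explained %.3f%%, pseudo-F %.3f, perm p %.4g (%d perms, seed %d, %s)\n",
    100 * x$var_explained, x$pseudo_F, x$perm_p, x$n_perm, x$seed, x$transform))
  invisible(x)
}

#' Strongest-associated variables of an RDA
#'
#' Variables ranked by absolute arrow score (constrained-axis loading),
#' descending; ties broken lexicographically. The study-style defaults are
#' k = 20 for OTU-level and k = 15 for gene-level runs.
#'
#' @param result an `rda_result`
#' @param k how many variables to return (>= 1)
#' @return data frame `variable`, `arrow_score`, signed
#' @export
top_arrows <- function(result, k) {
  if (k < 1) stop("k must be >= 1")
  a <- result$arrow_scores
  if (k > length(a)) {
    warning("k exceeds number of variables; returning all")
    k <- length(a)
  }
  o <- order(-abs(a), names(a))
  data.frame(variable = names(a)[o][seq_len(k)],
             arrow_score = unname(a[o][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Pathway scores from a gene-level table
#'
#' The pathway score of a sample is the sum of the counts of the genes
#' (models) assigned to that pathway. Catalog models absent from the table
#' are zero-filled with a warning.
#'
#' @param gene_table [labeled_matrix()] samples x models
#' @param catalog a `module_catalog`
#' @return [labeled_matrix()] samples x pathways
#' @export
pathway_scores <- function(gene_table, catalog) {
  .aggregate_columns(gene_table, module_members(catalog, "pathway"))
}

#' Per-pathway linear models against the SA score
#'
#' Ordinary least squares of each pathway score on the SA score over the
#' subjects present in both tables; slope, intercept, r-squared and the
#' two-sided p-value for the slope, with optional Benjamini-Hochberg
#' q-values across pathways.
#'
#' @param scores [labeled_matrix()] samples x pathways
#' @param sa named numeric SA scores
#' @param fdr add BH q-values (default `FALSE`)
#' @return data frame: `pathway`, `slope`, `intercept`, `r2`, `p_value`
#'   (and `q_value` with `fdr = TRUE`)
#' @export
pathway_lm <- function(scores, sa, fdr = FALSE) {
  common <- intersect(rownames(scores), names(sa))
  if (length(common) < 4) stop("need at least 4 overlapping subjects")
  y <- unclass(scores)[common, , drop = FALSE]
  x <- sa[common]
  out <- do.call(rbind, lapply(colnames(y), function(p) {
    fit <- lm(y[, p] ~ x)
    sm <- summary(fit)
    co <- sm$coefficients
    pv <- if (nrow(co) > 1) co["x", "Pr(>|t|)"] else NA_real_
    data.frame(pathway = p,
               slope = if (nrow(co) > 1) co["x", "Estimate"] else 0,
               intercept = co["(Intercept)", "Estimate"],
               r2 = sm$r.squared,
               p_value = pv, stringsAsFactors = FALSE)
  }))
  if (fdr) out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Row-max normalization
#'
#' Divides each row of a non-negative matrix by its maximum (zero rows
#' preserved), yielding values in `[0, 1]`. Idempotent.
#'
#' @param matrix a [labeled_matrix()] (e.g. pathways x subjects)
#' @return [labeled_matrix()] with `norm_state = "row_max"`
#' @export
rowmax_normalize <- function(matrix) {
  vals <- unclass(matrix)
  mx <- apply(vals, 1, max)
  out <- sweep(vals, 1, ifelse(mx > 0, mx, 1), "/")
  .set_norm_state(labeled_matrix(out, rownames(vals), colnames(vals),
                                 "raw_counts"), "row_max")
}

#' Heatmap-ready pathway table ordered by SA score
#'
#' Transposes a samples x pathways score table to pathways x subjects,
#' orders subjects by increasing SA score (young-looking to older-looking)
#' and normalizes each pathway row to its maximum.
#'
#' @param scores [labeled_matrix()] samples x pathways
#' @param sa named numeric SA scores
#' @return [labeled_matrix()] pathways x subjects, `row_max` normalized
#' @export
fig_pathway_table <- function(scores, sa) {
  common <- intersect(rownames(scores), names(sa))
  if (!length(common)) stop("no overlapping subjects")
  ord <- common[order(sa[common])]
  m <- t(unclass(scores)[ord, , drop = FALSE])
  rowmax_normalize(labeled_matrix(m, colnames(scores), ord))
}
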