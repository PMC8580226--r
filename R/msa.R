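# Progressive multiple sequence alignment of seed orthogroups: a UPGMA guide
# tree on k-mer distances ordering global profile-profile merges with affine
# gaps ("once a gap, always a gap"). No iterative refinement: the stage is
# deterministic and invariant to input order.

#' Construct a multiple sequence alignment object
#' @param row_ids sequence ids
#' @param rows equal-length gapped strings (gap character `-`)
#' @return an `msa` object
#' @export
msa <- function(row_ids, rows) {
  if (length(row_ids) != length(rows)) stop("row_ids and rows differ in length")
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("alignment rows differ in length")
  structure(list(row_ids = as.character(row_ids), rows = unname(rows),
                 n_cols = w), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$row_ids), x$n_cols))
  invisible(x)
}

#' Remove gaps from one alignment row
#' @param aln an `msa`
#' @param id row id
#' @return ungapped sequence string
#' @export
ungap_row <- function(aln, id) {
  i <- match(id, aln$row_ids)
  if (is.na(i)) stop("no such row: ", id)
  gsub("-", "", aln$rows[i], fixed = TRUE)
}

#' k-mer distance between two sequences
#'
#' `1 - |shared k-mers| / min(|kmers(a)|, |kmers(b)|)` on unique k-mer sets.
#' @param a,b amino-acid strings (length >= k)
#' @param k word size (default 3)
#' @return distance in `[0, 1]`
#' @export
kmer_distance <- function(a, b, k = 3) {
  if (k < 1) stop("k must be >= 1")
  if (nchar(a) < k || nchar(b) < k) stop("sequence shorter than k")
  ka <- .kmer_set(a, k); kb <- .kmer_set(b, k)
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

# Deterministic UPGMA with lexicographic tie-breaking. Clusters are labeled
# by their smallest member id; among equally close pairs the lexicographically
# smallest (label_a, label_b) pair is merged first.
.upgma <- function(d) {
  labs <- rownames(d)
  active <- lapply(labs, function(x) x)        # member id sets
  nodes <- as.list(labs)                       # nested-list subtrees
  sizes <- setNames(rep(1L, length(labs)), labs)
  names(active) <- names(nodes) <- labs
  dm <- d
  while (length(nodes) > 1) {
    ids <- names(nodes)
    best <- NULL
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      a <- ids[i]; b <- ids[j]
      pr <- sort(c(a, b))
      key <- c(dm[a, b], pr)
      if (is.null(best) || dm[a, b] < best$d - 1e-15 ||
          (abs(dm[a, b] - best$d) <= 1e-15 &&
           (pr[1] < best$a || (pr[1] == best$a && pr[2] < best$b))))
        best <- list(d = dm[a, b], a = pr[1], b = pr[2])
    }
    a <- best$a; b <- best$b
    new_lab <- min(a, b)
    other <- setdiff(ids, c(a, b))
    merged <- list(left = nodes[[a]], right = nodes[[b]])
    na <- sizes[[a]]; nb <- sizes[[b]]
    newd <- (dm[a, other] * na + dm[b, other] * nb) / (na + nb)
    keep <- c(other, new_lab)
    dm2 <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
    if (length(other)) {
      dm2[other, other] <- dm[other, other]
      dm2[new_lab, other] <- dm2[other, new_lab] <- newd
    }
    nodes[[a]] <- NULL; nodes[[b]] <- NULL
    sizes <- sizes[names(nodes)]
    nodes[[new_lab]] <- merged
    sizes[new_lab] <- na + nb
    dm <- dm2
  }
  nodes[[1]]
}

#' Guide tree for progressive alignment
#'
#' UPGMA on the pairwise [kmer_distance()] matrix, with deterministic
#' lexicographic tie-breaking, so the tree (and hence the alignment) does not
#' depend on input order.
#'
#' @param seqs protein record data frame (>= 2 rows)
#' @param k word size for the distance
#' @return nested list: leaves are protein ids, internal nodes are
#'   `list(left, right)`
#' @export
guide_tree <- function(seqs, k = 3) {
  if (nrow(seqs) < 2) stop("need at least 2 sequences")
  ids <- sort(seqs$protein_id)
  sq <- setNames(seqs$sequence, seqs$protein_id)[ids]
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- kmer_distance(sq[i], sq[j], k)
  .upgma(d)
}

.tree_leaves <- function(node) {
  if (is.character(node)) return(node)
  c(.tree_leaves(node$left), .tree_leaves(node$right))
}

# Merge two encoded profiles (integer matrices, 0 = gap) per the op list
# returned by the C++ aligner.
.apply_ops <- function(A, B, ops) {
  n <- length(ops)
  out <- matrix(0L, nrow(A) + nrow(B), n)
  ai <- 0L; bi <- 0L
  acol <- matrix(0L, nrow(A), n)
  bcol <- matrix(0L, nrow(B), n)
  for (t in seq_len(n)) {
    if (ops[t] != 3L) { ai <- ai + 1L; acol[, t] <- A[, ai] }
    if (ops[t] != 2L) { bi <- bi + 1L; bcol[, t] <- B[, bi] }
  }
  out[seq_len(nrow(A)), ] <- acol
  out[nrow(A) + seq_len(nrow(B)), ] <- bcol
  out
}

#' Progressive multiple sequence alignment
#'
#' Sequences are merged in guide-tree order by global (Needleman-Wunsch)
#' profile-profile alignment with affine gaps and terminal gaps penalized;
#' column pairs are scored by the mean substitution score over their residue
#' pairs. Gaps, once introduced, are never removed.
#'
#' @param seqs protein record data frame (>= 2 rows)
#' @param submat substitution matrix name
#' @param gap_open,gap_extend affine gap penalties
#' @param k guide-tree word size
#' @return an [msa] whose rows ungap exactly to the input sequences
#' @export
progressive_align <- function(seqs, submat = "BLOSUM62",
                              gap_open = 11, gap_extend = 1, k = 3) {
  if (nrow(seqs) < 2) stop("need at least 2 sequences")
  S <- .aa_submat(submat)
  sq <- setNames(seqs$sequence, seqs$protein_id)
  tree <- guide_tree(seqs, k)
  rec <- function(node) {
    if (is.character(node)) {
      prof <- matrix(.aa_encode(sq[[node]]), nrow = 1)
      return(list(ids = node, prof = prof))
    }
    L <- rec(node$left); R <- rec(node$right)
    ops <- .pp_align_cpp(L$prof, R$prof, S, gap_open, gap_extend)
    list(ids = c(L$ids, R$ids), prof = .apply_ops(L$prof, R$prof, ops))
  }
  res <- rec(tree)
  rows <- apply(res$prof, 1, .aa_decode)
  # canonical row order: lexicographic by id
  o <- order(res$ids)
  msa(res$ids[o], rows[o])
}
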