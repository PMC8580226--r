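# Orthologous-group inference across the reference proteome panel:
# exact Smith-Waterman similarity, reciprocal-best-hit clustering with
# in-paralog merging, the single-copy core, and a neighbor-joining panel
# phylogeny from a concatenated core alignment.

#' Smith-Waterman local alignment score
#'
#' Exact local alignment with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`). Symmetric in its arguments.
#'
#' @param a,b amino-acid strings
#' @param submat substitution matrix name (default BLOSUM62)
#' @param gap_open,gap_extend affine gap penalties (positive costs)
#' @return alignment score (matrix units); 0 when no positive-scoring local
#'   alignment exists
#' @export
local_align_score <- function(a, b, submat = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  .sw_score_cpp(.aa_encode(a), .aa_encode(b), .aa_submat(submat),
                gap_open, gap_extend)
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Build the all-vs-all similarity graph of a protein panel
#'
#' Scores inter-genome pairs (and intra-genome pairs, needed for in-paralog
#' detection) by exact Smith-Waterman. An optional k-mer prefilter skips
#' pairs sharing no k-mer. `norm_score` is the raw score divided by the
#' self-score of the shorter sequence, clamped to `[0, 1]`; edges with
#' `norm_score` below `min_norm_score` are dropped.
#'
#' @param proteins protein record data frame (>= 2 rows)
#' @param min_norm_score edge retention threshold (default 0.3)
#' @param prefilter_kmer k for the shared-k-mer prefilter; `NA` disables it
#' @param submat,gap_open,gap_extend see [local_align_score()]
#' @return data frame of edges: `protein_a`, `protein_b` (a < b), `genome_a`,
#'   `genome_b`, `score`, `norm_score`
#' @export
build_similarity_graph <- function(proteins, min_norm_score = 0.3,
                                   prefilter_kmer = 4, submat = "BLOSUM62",
                                   gap_open = 11, gap_extend = 1) {
  if (nrow(proteins) < 2) stop("need at least 2 proteins")
  ord <- order(proteins$protein_id)
  proteins <- proteins[ord, , drop = FALSE]
  n <- nrow(proteins)
  S <- .aa_submat(submat)
  enc <- lapply(proteins$sequence, .aa_encode)
  self <- vapply(enc, function(e) .sw_score_cpp(e, e, S, gap_open, gap_extend),
                 0.0)
  km <- NULL
  if (!is.na(prefilter_kmer))
    km <- lapply(proteins$sequence, .kmer_set, k = prefilter_kmer)
  lens <- nchar(proteins$sequence)
  out <- vector("list", n)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    if (!is.null(km))
      js <- js[vapply(js, function(j) any(km[[i]] %in% km[[j]]), TRUE)]
    if (!length(js)) next
    sc <- vapply(js, function(j)
      .sw_score_cpp(enc[[i]], enc[[j]], S, gap_open, gap_extend), 0.0)
    # self-score of the shorter sequence; length ties resolved by protein_id
    denom <- ifelse(lens[js] < lens[i], self[js],
             ifelse(lens[js] > lens[i], self[i], pmin(self[i], self[js])))
    ns <- pmin(pmax(sc / denom, 0), 1)
    keep <- ns >= min_norm_score
    if (!any(keep)) next
    js <- js[keep]
    out[[i]] <- data.frame(
      protein_a = proteins$protein_id[i], protein_b = proteins$protein_id[js],
      genome_a = proteins$genome_id[i], genome_b = proteins$genome_id[js],
      score = sc[keep], norm_score = ns[keep], stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(edges))
    edges <- data.frame(protein_a = character(), protein_b = character(),
                        genome_a = character(), genome_b = character(),
                        score = numeric(), norm_score = numeric())
  rownames(edges) <- NULL
  edges
}

#' Cluster proteins into orthologous groups
#'
#' Reciprocal-best-hit (RBH) clustering: for each ordered genome pair the
#' best-scoring hit per query (by `norm_score`, ties broken by protein id) is
#' marked; inter-genome edges are kept iff reciprocal-best. Intra-genome
#' pairs scoring higher than both proteins' best inter-genome hits are merged
#' as in-paralogs. Connected components of the kept graph are the groups;
#' proteins without kept edges become singleton groups. Group ids are
#' assigned deterministically from the sorted member lists.
#'
#' @param edges edge data frame from [build_similarity_graph()]
#' @param proteins the protein record data frame the edges were built from
#' @param seed_genes optional seed-gene table; groups containing a protein
#'   whose id matches a `locus_tag` or `gene_symbol` are flagged
#' @return data frame with columns `group_id`, `genome_id`, `protein_id`,
#'   `is_seed_group`
#' @export
cluster_orthogroups <- function(edges, proteins, seed_genes = NULL) {
  pid <- proteins$protein_id
  gid <- setNames(proteins$genome_id, pid)
  keep_pairs <- character(0)
  if (nrow(edges)) {
    inter <- edges[edges$genome_a != edges$genome_b, , drop = FALSE]
    intra <- edges[edges$genome_a == edges$genome_b, , drop = FALSE]
    best_inter <- setNames(rep(-Inf, length(pid)), pid)
    if (nrow(inter)) {
      # directed view: each edge seen from both endpoints
      dir <- data.frame(
        q = c(inter$protein_a, inter$protein_b),
        t = c(inter$protein_b, inter$protein_a),
        qg = c(inter$genome_a, inter$genome_b),
        tg = c(inter$genome_b, inter$genome_a),
        ns = c(inter$norm_score, inter$norm_score), stringsAsFactors = FALSE)
      # best hit per (query, target genome); ties -> lexicographic target id
      dir <- dir[order(dir$q, dir$tg, -dir$ns, dir$t), , drop = FALSE]
      bh <- dir[!duplicated(dir[c("q", "tg")]), , drop = FALSE]
      bkey <- paste(bh$q, bh$t)
      rbh <- bh[paste(bh$t, bh$q) %in% bkey, , drop = FALSE]
      keep_pairs <- unique(vapply(seq_len(nrow(rbh)), function(i)
        paste(sort(c(rbh$q[i], rbh$t[i])), collapse = "\r"), ""))
      mx <- tapply(dir$ns, dir$q, max)
      best_inter[names(mx)] <- mx
    }
    if (nrow(intra)) {
      inp <- intra$norm_score > pmax(best_inter[intra$protein_a],
                                     best_inter[intra$protein_b])
      keep_pairs <- c(keep_pairs,
                      paste(intra$protein_a[inp], intra$protein_b[inp],
                            sep = "\r"))
    }
  }
  # connected components over all proteins
  g <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(length(pid), name = sort(pid))
  if (length(keep_pairs)) {
    ab <- strsplit(keep_pairs, "\r", fixed = TRUE)
    g <- igraph::add_edges(g, t(do.call(rbind, ab)))
  }
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, "", 1L))]
  wid <- max(4L, nchar(length(members)))
  res <- do.call(rbind, lapply(seq_along(members), function(i) {
    data.frame(group_id = sprintf("OG%0*d", wid, i),
               genome_id = unname(gid[members[[i]]]),
               protein_id = members[[i]], stringsAsFactors = FALSE)
  }))
  seeds <- character(0)
  if (!is.null(seed_genes))
    seeds <- tolower(c(seed_genes$locus_tag, seed_genes$gene_symbol))
  hit <- tolower(res$protein_id) %in% seeds[nzchar(seeds)]
  res$is_seed_group <- res$group_id %in% unique(res$group_id[hit])
  rownames(res) <- NULL
  res
}

#' Single-copy core of an orthogroup set
#'
#' Keeps exactly the groups that have one member in every panel genome.
#' @param groups orthogroup data frame from [cluster_orthogroups()]
#' @param genome_ids the full panel genome id set
#' @return subset of `groups` (possibly empty)
#' @export
single_copy_core <- function(groups, genome_ids) {
  ok <- vapply(split(groups$genome_id, groups$group_id), function(g)
    length(g) == length(genome_ids) && !anyDuplicated(g) &&
      all(genome_ids %in% g), TRUE)
  groups[groups$group_id %in% names(ok)[ok], , drop = FALSE]
}

#' Pairwise p-distances from concatenated core-gene alignments
#'
#' Alignments (one per single-copy core group, rows labeled by genome) are
#' concatenated per genome; the distance between two genomes is
#' `1 - identical / compared` over columns where neither row has a gap.
#'
#' @param core_groups single-copy core orthogroup data frame
#' @param alignments named list of [msa] objects, one per `group_id`, with
#'   `row_ids` equal to genome ids
#' @return symmetric numeric matrix with zero diagonal
#' @export
concat_core_distances <- function(core_groups, alignments) {
  gids <- sort(unique(core_groups$genome_id))
  use <- intersect(unique(core_groups$group_id), names(alignments))
  if (!length(use)) stop("no alignments for core groups")
  rows <- setNames(rep("", length(gids)), gids)
  for (gr in use) {
    aln <- alignments[[gr]]
    miss <- setdiff(gids, aln$row_ids)
    if (length(miss))
      stop("alignment for ", gr, " missing genome(s): ",
           paste(miss, collapse = ", "))
    rows <- paste0(rows, setNames(aln$rows, aln$row_ids)[gids])
  }
  n <- length(gids)
  chars <- lapply(rows, function(r) strsplit(r, "", fixed = TRUE)[[1]])
  d <- matrix(0, n, n, dimnames = list(gids, gids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- chars[[i]]; b <- chars[[j]]
    cmp <- a != "-" & b != "-"
    d[i, j] <- d[j, i] <-
      if (any(cmp)) 1 - sum(a[cmp] == b[cmp]) / sum(cmp) else 0
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}); negative branch lengths are
#' clamped to zero. NJ recovers the generating tree exactly on additive
#' distances.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa)
#' @return newick string (terminated by `;`)
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::write.tree(tr)
}
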