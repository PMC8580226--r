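test_that("local alignment score matches hand-derived values", {
  # identical triple: sum of BLOSUM62 diagonal entries A=4, C=9, D=6
  expect_equal(local_align_score("ACD", "ACD"), 19)
  # every BLOSUM62 score of {A,C,D} x W is negative: empty local alignment
  expect_equal(local_align_score("ACD", "WWW"), 0)
  expect_equal(local_align_score("MKVL", "MKVL"),
               local_align_score("MKVL", "MKVL"))
  s1 <- local_align_score("MKVLAPGH", "MKVAPGH")
  expect_equal(local_align_score("MKVAPGH", "MKVLAPGH"), s1)
  expect_error(local_align_score("", "ACD"), "empty")
})

test_that("exact Smith-Waterman agrees with the Biostrings reference", {
  set.seed(11)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (i in 1:12) {
    a <- random_aa_seq(sample(10:40, 1))
    b <- if (i %% 3 == 0) a else random_aa_seq(sample(10:40, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
    expect_equal(local_align_score(a, b), max(ref, 0))
  }
})

test_that("similarity graph normalizes by the shorter self-score", {
  s <- random_aa_seq(40)
  prot <- prot_df(c("a1", "b1"), c("gA", "gB"), c(s, s))
  e <- build_similarity_graph(prot)
  expect_equal(nrow(e), 1)
  expect_equal(e$norm_score, 1.0)
  expect_true(e$protein_a < e$protein_b)

  # unrelated random pair: both orders below the 0.3 default threshold
  set.seed(5)
  prot2 <- prot_df(c("a1", "b1"), c("gA", "gB"),
                   c(random_aa_seq(60), random_aa_seq(60)))
  expect_equal(nrow(build_similarity_graph(prot2)), 0)
})

test_that("similarity graph is invariant to input permutation", {
  set.seed(9)
  base <- random_aa_seq(50)
  fam <- evolve_family(base, 4, 0.1, 0, seed = 3)
  prot <- prot_df(paste0("p", 1:4), paste0("g", 1:4), fam)
  e1 <- build_similarity_graph(prot)
  e2 <- build_similarity_graph(prot[c(3, 1, 4, 2), ])
  rownames(e1) <- rownames(e2) <- NULL
  expect_equal(e1, e2)
})

test_that("RBH clustering groups a three-genome family and leaves decoys alone", {
  set.seed(21)
  base <- random_aa_seq(60)
  fam <- evolve_family(base, 3, 0.1, 0, seed = 4)
  prot <- prot_df(c("fA", "fB", "fC", "dA", "dB"),
                  c("gA", "gB", "gC", "gA", "gB"),
                  c(fam, random_aa_seq(60), random_aa_seq(60)))
  gr <- cluster_orthogroups(build_similarity_graph(prot), prot)
  # partition property
  expect_setequal(gr$protein_id, prot$protein_id)
  expect_equal(anyDuplicated(gr$protein_id), 0)
  fam_gr <- unique(gr$group_id[gr$protein_id %in% c("fA", "fB", "fC")])
  expect_length(fam_gr, 1)
  expect_equal(sum(gr$group_id == fam_gr), 3)
})

test_that("recent in-paralogs merge into the cross-genome group", {
  set.seed(31)
  base <- random_aa_seq(60)
  f1 <- evolve_family(base, 1, 0.12, 0, seed = 6)        # genome A copy 1
  f2 <- evolve_family(f1, 1, 0.02, 0, seed = 7)          # recent duplicate
  fB <- evolve_family(base, 1, 0.12, 0, seed = 8)        # genome B ortholog
  prot <- prot_df(c("A_f1", "A_f2", "B_f"), c("gA", "gA", "gB"),
                  c(f1, f2, fB))
  gr <- cluster_orthogroups(build_similarity_graph(prot), prot)
  expect_length(unique(gr$group_id), 1)
})

test_that("an empty edge list yields singleton groups", {
  prot <- prot_df(c("a", "b"), c("gA", "gB"), c("MKV", "ACD"))
  edges <- build_similarity_graph(prot)[0, ]
  gr <- cluster_orthogroups(edges, prot)
  expect_equal(length(unique(gr$group_id)), 2)
})

test_that("clustering is idempotent and order-invariant", {
  pan <- simulate_panel(n_genomes = 3, n_families = 2, n_decoys = 2,
                        seq_length = 80, seed = 12)
  prot <- pan$proteins
  g1 <- cluster_orthogroups(build_similarity_graph(prot), prot)
  g2 <- cluster_orthogroups(build_similarity_graph(prot[rev(seq_len(nrow(prot))), ]),
                            prot[sample(nrow(prot)), ])
  o1 <- g1[order(g1$protein_id), c("group_id", "protein_id")]
  o2 <- g2[order(g2$protein_id), c("group_id", "protein_id")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("seed-gene matches flag their orthogroup", {
  prot <- prot_df(c("lasA", "other"), c("gA", "gB"), c("MKVLA", "ACDEF"))
  seeds <- data.frame(gene_symbol = "lasA", locus_tag = "", organism = "x",
                      pathway = "Proteolysis", stringsAsFactors = FALSE)
  gr <- cluster_orthogroups(build_similarity_graph(prot)[0, ], prot, seeds)
  expect_true(gr$is_seed_group[gr$protein_id == "lasA"])
  expect_false(gr$is_seed_group[gr$protein_id == "other"])
})

test_that("single_copy_core applies the exactly-one-per-genome rule", {
  gr <- data.frame(
    group_id = c("G1", "G1", "G1", "G2", "G2", "G2", "G2", "G3", "G3"),
    genome_id = c("a", "b", "c", "a", "a", "b", "c", "a", "b"),
    protein_id = paste0("p", 1:9), stringsAsFactors = FALSE)
  core <- single_copy_core(gr, c("a", "b", "c"))
  expect_setequal(unique(core$group_id), "G1")   # G2 duplicated, G3 missing c
  expect_true(all(core$group_id %in% gr$group_id))
})

test_that("concatenated p-distances follow the definition", {
  a1 <- msa(c("gA", "gB"), c("AC-D", "AC-E"))
  gr <- data.frame(group_id = "G1", genome_id = c("gA", "gB"),
                   protein_id = c("x", "y"))
  d <- concat_core_distances(gr, list(G1 = a1))
  expect_equal(d["gA", "gB"], 1 - 2 / 3)
  expect_equal(d["gA", "gA"], 0)
  expect_equal(d, t(d))

  ident <- msa(c("gA", "gB"), c("MKV", "MKV"))
  expect_equal(concat_core_distances(gr, list(G1 = ident))["gA", "gB"], 0)

  bad <- msa(c("gA", "gZ"), c("MKV", "MKV"))
  expect_error(concat_core_distances(gr, list(G1 = bad)), "missing genome")
})

test_that("neighbor joining recovers an additive four-taxon tree exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  d <- ape::cophenetic.phylo(tr)
  nwk <- nj_tree(d)
  expect_match(nwk, ";$")
  back <- ape::read.tree(text = nwk)
  expect_equal(ape::dist.topo(ape::unroot(tr), back), setNames(0, "PH85"),
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(back)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
})

test_that("equal distances give equal terminal branches; order is immaterial", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tr <- ape::read.tree(text = nj_tree(d))
  term <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_true(diff(range(term)) < 1e-12)

  # permuting taxa of an additive (uniquely resolvable) matrix gives an
  # isomorphic tree
  tra <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  da <- ape::cophenetic.phylo(tra)
  perm <- c(3, 1, 4, 2)
  t1 <- ape::read.tree(text = nj_tree(da))
  t2 <- ape::read.tree(text = nj_tree(da[perm, perm]))
  expect_equal(ape::dist.topo(t1, t2), setNames(0, "PH85"), ignore_attr = TRUE)

  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
})
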