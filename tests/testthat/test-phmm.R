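test_that("match columns are flagged by strict gap-fraction rule", {
  gapless <- msa(c("a", "b"), c("MKV", "MKV"))
  expect_equal(select_match_columns(gapless), rep(TRUE, 3))

  # 3/4 gaps -> insert; exactly 50% gaps -> insert (strict inequality)
  aln <- msa(letters[1:4], c("M-KV", "M--V", "M--V", "M-XV"))
  flags <- select_match_columns(aln, 0.5)
  expect_equal(flags, c(TRUE, FALSE, FALSE, TRUE))
  half <- msa(letters[1:4], c("MA", "M-", "MA", "M-"))
  expect_equal(select_match_columns(half, 0.5), c(TRUE, FALSE))

  allgap <- msa(c("a", "b"), c("--", "--"))
  expect_error(select_match_columns(allgap), "no match columns")
})

test_that("profile estimators follow the stated arithmetic", {
  aln <- msa(c("a", "b"), c("AC", "AC"))
  h <- build_profile(aln, pseudocount = 1, name = "t")
  expect_equal(unname(h$match_emissions[1, "A"]), 3 / 22)
  expect_equal(unname(h$match_emissions[1, "C"]), 1 / 22)

  # no-pseudocount limit: column AAAA -> P(A) = 1
  aln4 <- msa(letters[1:4], c("AG", "AG", "AG", "AG"))
  h0 <- build_profile(aln4, pseudocount = 0)
  expect_equal(unname(h0$match_emissions[1, "A"]), 1)
  expect_equal(sum(h0$match_emissions[1, -1]), 0)

  # gapless alignment transitions: P(M->M) = (count+1)/(count+3)
  h4 <- build_profile(aln4, pseudocount = 1)
  expect_equal(unname(h4$transitions[1, "MM"]), (4 + 1) / (4 + 3))
  # all probability rows sum to 1 within 1e-9
  expect_equal(rowSums(h4$match_emissions), rep(1, 2), tolerance = 1e-9)
  expect_equal(rowSums(h4$insert_emissions), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(h4$transitions[1, c("MM", "MI", "MD")]), 1, tolerance = 1e-9)
  expect_equal(sum(h4$transitions[1, c("IM", "II")]), 1, tolerance = 1e-9)
  expect_equal(sum(h4$transitions[1, c("DM", "DD")]), 1, tolerance = 1e-9)
})

test_that("forward and Viterbi match exhaustive path enumeration", {
  set.seed(1)
  for (case in 1:40) {
    M <- sample(1:3, 1)
    h <- random_toy_hmm(M, seed = 1000 + case)
    s <- random_aa_seq(sample(1:5, 1))
    oracle <- enumerate_paths(h, s)
    expect_equal(score_forward(h, s), oracle$forward_bits, tolerance = 1e-9)
    v <- score_viterbi(h, s)
    expect_equal(v$bits, oracle$viterbi_bits, tolerance = 1e-9)
    expect_lte(v$bits, score_forward(h, s) + 1e-9)
  }
})

test_that("X residues emit the background: all-X scores are transition-only", {
  h <- random_toy_hmm(3, seed = 9)
  sx <- "XXXX"
  # oracle with emission odds forced to 1 everywhere == all-X enumeration
  oracle <- enumerate_paths(h, sx)
  expect_equal(score_forward(h, sx), oracle$forward_bits, tolerance = 1e-9)
})

test_that("degenerate single-path model has viterbi == forward", {
  # M = 1: entry probability 1, exit probability 1, emission concentrated on
  # A; against the one-residue sequence "A" exactly one path carries all mass
  me <- matrix(0, 1, 20, dimnames = list(NULL, skincomet:::AA20))
  me[1, "A"] <- 1
  tr <- matrix(NA_real_, 1, 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  h <- structure(list(name = "deg", M = 1, match_emissions = me,
                      insert_emissions = matrix(1 / 20, 2, 20),
                      transitions = tr,
                      background = setNames(rep(1 / 20, 20), skincomet:::AA20),
                      ga_bits = NULL, ga_overlap = FALSE, members = character(0)),
                 class = "profile_hmm")
  expect_equal(score_forward(h, "A"), score_viterbi(h, "A")$bits,
               tolerance = 1e-12)
  expect_equal(score_forward(h, "A"), log2(1 / (1 / 20)), tolerance = 1e-12)
  expect_equal(score_viterbi(h, "A")$path, "M1")
})

test_that("scaled and log-space forward kernels agree", {
  # the production kernel works in rescaled linear space; the log-space
  # kernel is retained as an internal cross-check
  set.seed(6)
  for (i in 1:10) {
    h <- random_toy_hmm(sample(2:6, 1), seed = 300 + i)
    s <- random_aa_seq(sample(5:30, 1))
    a <- skincomet:::.phmm_dp_args(h, s)
    nats_log <- skincomet:::.phmm_forward_cpp(
      a$em, a$lMM, a$lMI, a$lMD, a$lIM, a$lII, a$lDM, a$lDD, a$lEntry, a$lExit)
    expect_equal(score_forward(h, s), nats_log / log(2), tolerance = 1e-9)
  }
})

test_that("training members outscore shuffled same-composition sequences", {
  base <- random_aa_seq(80)
  fam <- evolve_family(base, 4, 0.1, 0, seed = 5)
  aln <- progressive_align(prot_df(paste0("m", 1:4), "g", fam))
  h <- build_profile(aln)
  for (s in fam) {
    shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_gt(score_forward(h, s), score_forward(h, shuf))
  }
})

test_that("GA calibration is the stated midpoint rule", {
  h <- random_toy_hmm(2, seed = 2)
  fake_scores <- c(p1 = 41.9, p2 = 55.0, n1 = 12.3, n2 = 30.1)
  pos <- prot_df(c("p1", "p2"), "g", c("AC", "AD"))
  neg <- prot_df(c("n1", "n2"), "g", c("WW", "WY"))
  h2 <- calibrate_ga(h, pos, neg, scores = fake_scores)
  expect_equal(h2$ga_bits, 36.0)
  expect_false(h2$ga_overlap)

  # boundary: equal extremes -> GA = value, overlap flagged
  h3 <- calibrate_ga(h, pos[1, ], neg[1, ],
                     scores = c(p1 = 10, n1 = 10))
  expect_equal(h3$ga_bits, 10)
  expect_true(h3$ga_overlap)

  expect_error(calibrate_ga(h, pos[0, ], neg), "empty positives")
  expect_warning(h4 <- calibrate_ga(h, pos, neg[0, ], scores = fake_scores),
                 "no negatives")
  expect_equal(h4$ga_bits, 41.9 - 0.5)
})

test_that("GA calibration is monotone in added scores", {
  h <- random_toy_hmm(2, seed = 3)
  pos <- prot_df(c("p1", "p2"), "g", c("AC", "AD"))
  neg <- prot_df(c("n1", "n2"), "g", c("WW", "WY"))
  sc <- c(p1 = 40, p2 = 50, n1 = 10, n2 = 20)
  ga0 <- calibrate_ga(h, pos, neg, scores = sc)$ga_bits
  # higher-scoring extra negative never lowers GA
  sc2 <- c(sc, n3 = 25)
  ga1 <- calibrate_ga(h, pos, rbind(neg, prot_df("n3", "g", "WF")),
                      scores = sc2)$ga_bits
  expect_gte(ga1, ga0)
  # lower-scoring extra positive never raises GA
  sc3 <- c(sc, p3 = 35)
  ga2 <- calibrate_ga(h, rbind(pos, prot_df("p3", "g", "AE")), neg,
                      scores = sc3)$ga_bits
  expect_lte(ga2, ga0)
})

test_that("model files round-trip scores, GA and flags", {
  pan <- simulate_panel(n_genomes = 3, n_families = 2, n_decoys = 2,
                        seq_length = 60, seed = 23)
  built <- suppressWarnings(build_panel_models(pan$proteins))
  f <- tempfile(fileext = ".hmm")
  write_model_file(built$models, f)
  back <- read_model_file(f)
  expect_setequal(names(back), names(built$models))
  set.seed(4)
  tests <- c(pan$proteins$sequence[1:5],
             replicate(20, random_aa_seq(sample(20:60, 1))))
  for (nm in names(built$models)) {
    expect_identical(back[[nm]]$ga_bits, built$models[[nm]]$ga_bits)
    for (s in tests)
      expect_equal(score_forward(back[[nm]], s),
                   score_forward(built$models[[nm]], s), tolerance = 1e-9)
  }
})

test_that("model files without GA load but refuse thresholded scans", {
  h <- random_toy_hmm(2, seed = 8)
  f <- tempfile()
  write_model_file(list(h), f)
  back <- read_model_file(f)
  expect_null(back[[1]]$ga_bits)
  expect_error(score_report(back[[1]], prot_df("p", "g", "ACDE")), "GA")
})

test_that("truncated and malformed model files fail loudly", {
  h <- random_toy_hmm(2, seed = 8)
  f <- tempfile()
  write_model_file(list(h), f)
  lines <- readLines(f)
  writeLines(lines[1:5], f)
  expect_error(read_model_file(f), "line")
  writeLines(c("SKINCOMET-HMM 1.0", "BOGUS x"), f)
  expect_error(read_model_file(f), "line 2")
  writeLines(lines[-length(lines)], f)   # drop the // terminator
  expect_error(read_model_file(f), "terminator|truncated")
})
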