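make_pheno <- function(n, seed = 1, noise = 0.5) {
  simulate_phenotypes(n, noise_sd = noise, seed = seed)
}

test_that("SA score behaves as an oriented z-score mean", {
  # identical subjects: no variation, all SA = 0
  m <- matrix(5, 4, 8, dimnames = list(paste0("S", 1:4), PHENO_MEASUREMENTS))
  expect_warning(sa0 <- compute_sa_score(as.data.frame(m)), "zero-variance")
  expect_equal(unname(sa0), rep(0, 4))

  # the subject maximal on every oriented column has the highest SA
  sim <- make_pheno(10, seed = 2, noise = 0)
  ph <- sim$phenotypes
  top <- rownames(ph)[which.max(sim$truth$age)]
  sa <- compute_sa_score(ph)
  expect_equal(names(which.max(sa)), top)

  # flipping one column's orientation negates exactly that contribution
  orient <- DEFAULT_ORIENTATION
  sa_a <- compute_sa_score(ph, orient)
  orient["roughness"] <- -1
  sa_b <- compute_sa_score(ph, orient)
  zr <- scale(ph[, "roughness"])[, 1]
  expect_equal(sa_a - sa_b, setNames(2 * zr / 8, rownames(ph)),
               tolerance = 1e-12)

  expect_error(compute_sa_score(ph[1:2, ]), "3 subjects")
  expect_error(compute_sa_score(ph[, -1]), "missing measurement")
})

test_that("SA score is invariant to affine rescaling of any column", {
  ph <- make_pheno(12, seed = 3)$phenotypes
  sa1 <- compute_sa_score(ph)
  ph2 <- ph
  ph2$roughness <- 100 + 7 * ph2$roughness
  expect_equal(compute_sa_score(ph2), sa1, tolerance = 1e-12)
})

test_that("RDA projections match first principles", {
  set.seed(10)
  n <- 12
  # constraint constructed orthogonal to every centered response column
  x <- rnorm(n)
  xc <- x - mean(x)
  Y0 <- matrix(rnorm(n * 5), n, 5)
  Y <- apply(Y0, 2, function(col) col - xc * sum(col * xc) / sum(xc^2))
  Y <- Y - min(Y)  # keep non-negative for the container
  r <- rda(labeled_matrix(Y, paste0("S", 1:n), paste0("f", 1:5)), x,
           transform = "none", n_perm = 19, seed = 1)
  expect_lt(r$var_explained, 1e-12)

  # noiseless rank-1 response: all variance explained
  load <- runif(5, 0.5, 2)
  Y1 <- outer(xc, load); Y1 <- Y1 - min(Y1)
  r1 <- rda(labeled_matrix(Y1, paste0("S", 1:n), paste0("f", 1:5)), x,
            transform = "none", n_perm = 19, seed = 1)
  expect_equal(r1$var_explained, 1, tolerance = 1e-9)

  # SS decomposition: fitted + residual = total
  Y2 <- matrix(runif(n * 4), n, 4)
  r2 <- rda(labeled_matrix(Y2, paste0("S", 1:n), paste0("f", 1:4)), x,
            transform = "hellinger", n_perm = 19, seed = 1)
  expect_gte(r2$var_explained, 0)
  expect_lte(r2$var_explained, 1)
})

test_that("RDA variance explained equals the per-column regression oracle", {
  set.seed(20)
  for (i in 1:15) {
    n <- sample(6:25, 1); p <- sample(2:15, 1)
    Y <- matrix(runif(n * p), n, p)
    x <- rnorm(n)
    r <- rda(labeled_matrix(Y, paste0("S", 1:n), paste0("f", 1:p)), x,
             transform = "none", n_perm = 9, seed = i)
    expect_equal(r$var_explained, rda_oracle_var(Y, x), tolerance = 1e-9)
  }
})

test_that("RDA agrees with vegan on variance explained and F", {
  skip_if_not_installed("vegan")
  set.seed(33)
  n <- 20; p <- 8
  Y <- matrix(runif(n * p), n, p)
  x <- rnorm(n)
  r <- rda(labeled_matrix(Y, paste0("S", 1:n), paste0("f", 1:p)), x,
           transform = "none", n_perm = 99, seed = 2)
  v <- vegan::rda(Y ~ x)
  expect_equal(r$var_explained,
               unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-9)
  av <- vegan::anova.cca(v, permutations = 99)
  expect_equal(r$pseudo_F, av$F[1], tolerance = 1e-9)
})

test_that("permutation p is invariant to affine rescaling of the constraint", {
  set.seed(8)
  n <- 14
  Y <- matrix(runif(n * 6), n, 6)
  x <- rnorm(n)
  m <- labeled_matrix(Y, paste0("S", 1:n), paste0("f", 1:6))
  r1 <- rda(m, x, transform = "none", n_perm = 49, seed = 5)
  r2 <- rda(m, 3 * x + 2, transform = "none", n_perm = 49, seed = 5)
  expect_equal(r1$perm_p, r2$perm_p)
  expect_equal(r1$var_explained, r2$var_explained, tolerance = 1e-12)

  expect_error(rda(m, rep(1, n), n_perm = 9), "constant")
  expect_error(rda(m, x, n_perm = 0), "n_perm")
  expect_error(rda(m[1:3, ], x[1:3], n_perm = 9), "4 samples")
})

test_that("top_arrows ranks by absolute loading with stated defaults", {
  r <- structure(list(arrow_scores = c(a = 0.1, b = -0.9, c = 0.5, d = 0,
                                       e = -0.5)),
                 class = "rda_result")
  ta <- top_arrows(r, 3)
  expect_equal(ta$variable, c("b", "c", "e"))   # tie 0.5 broken c < e
  expect_equal(ta$arrow_score[1], -0.9)
  expect_warning(all_of_them <- top_arrows(r, 10), "all")
  expect_equal(nrow(all_of_them), 5)
  expect_equal(all_of_them$variable[5], "d")    # zero loading last
  expect_error(top_arrows(r, 0), "k must be")
})

test_that("pathway scores sum member genes (histidine example)", {
  genes <- labeled_matrix(rbind(S1 = c(2, 1, 0), S2 = c(1, 1, 1)),
                          c("S1", "S2"), c("hutH", "hutU", "hutL"))
  cat <- data.frame(pathway = rep("Histidine metabolism", 3),
                    module_id = rep("his", 3),
                    model_name = c("hutH", "hutU", "hutL"))
  class(cat) <- c("module_catalog", "data.frame")
  ps <- pathway_scores(genes, cat)
  expect_equal(unclass(ps)["S1", "Histidine metabolism"], 3)
  expect_equal(rowSums(unclass(ps)), rowSums(unclass(genes)))
  zero <- labeled_matrix(matrix(0, 2, 3), c("S1", "S2"),
                         c("hutH", "hutU", "hutL"))
  expect_true(all(unclass(pathway_scores(zero, cat)) == 0))
})

test_that("pathway linear models recover exact fits and validate input", {
  sa <- setNames(seq(-2, 2, length.out = 10), paste0("S", 1:10))
  y <- 2 * sa + 1
  scores <- labeled_matrix(matrix(y - min(y), ncol = 1,
                                  dimnames = list(names(sa), "pw")),
                           names(sa), "pw")
  # noiseless construction: summary.lm warns about the perfect fit
  fit <- suppressWarnings(pathway_lm(scores, sa))
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1 - min(y), tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_error(pathway_lm(scores[1:3, , drop = FALSE], sa[1:3]), "4 overlapping")
  # BH q-values appear on request
  fit2 <- suppressWarnings(pathway_lm(scores, sa, fdr = TRUE))
  expect_true("q_value" %in% names(fit2))
})

test_that("row-max normalization and the SA-ordered export", {
  m <- labeled_matrix(rbind(p1 = c(3, 6, 0), p2 = c(0, 0, 0)),
                      c("p1", "p2"), c("s1", "s2", "s3"))
  n <- rowmax_normalize(m)
  expect_equal(unclass(n)["p1", ], c(s1 = 0.5, s2 = 1.0, s3 = 0.0))
  expect_equal(unclass(n)["p2", ], c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(norm_state(n), "row_max")
  expect_equal(unclass(rowmax_normalize(n)), unclass(n), ignore_attr = TRUE)

  scores <- labeled_matrix(rbind(S1 = c(1, 4), S2 = c(2, 2), S3 = c(4, 1)),
                           paste0("S", 1:3), c("pwA", "pwB"))
  sa <- c(S1 = 0.5, S2 = -1, S3 = 0)
  ft <- fig_pathway_table(scores, sa)
  expect_equal(colnames(ft), c("S2", "S3", "S1"))   # increasing SA
  expect_equal(unclass(ft)["pwA", "S3"], 1)         # row max is 1
})
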