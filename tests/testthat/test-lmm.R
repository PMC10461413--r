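test_that("centered kinship matches hand arithmetic and degenerate cases", {
  # 3 lines x 2 variants, columns [0,1,1] and [0,0,1]
  g <- genotype_matrix(matrix(c(0, 1, 1, 0, 0, 1), 3, 2),
                       line_ids = c("a", "b", "c"),
                       variant_ids = c("v1", "v2"))
  K <- centered_kinship(g)
  expect_equal(K[1, 1], 5 / 18)
  expect_equal(K[1, 2], -1 / 18)
  expect_equal(K, t(K))

  # constant columns contribute nothing (here: dropped, so error if alone)
  g2 <- genotype_matrix(matrix(c(0, 0, 0), 3, 1),
                        line_ids = c("a", "b", "c"), variant_ids = "v1")
  expect_error(centered_kinship(g2), "polymorphic")

  # duplicate lines have identical kinship entries
  g3 <- genotype_matrix(matrix(c(0, 0, 1, 1, 1, 0, 0, 1), 4, 2),
                        line_ids = c("a", "a2", "b", "c"),
                        variant_ids = c("v1", "v2"))
  g3[2, ] <- g3[1, ]
  K3 <- centered_kinship(g3)
  expect_equal(K3[1, 1], K3[2, 2])
  expect_equal(K3[1, 1], K3[1, 2])

  # centered construction: row sums ~ 0 without missing data
  g4 <- random_geno(6, 20, seed = 2)
  expect_lt(max(abs(rowSums(centered_kinship(g4)))), 1e-10)
})

test_that("eigen-trick likelihood equals dense likelihood on random instances", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(4:8, 1)
    g <- random_geno(n, 25, seed = s + 50)
    K <- centered_kinship(g)
    y <- rnorm(n)
    W <- cbind(1, rnorm(n))
    eig <- eigen(K, symmetric = TRUE)
    yr <- drop(crossprod(eig$vectors, y))
    Wr <- crossprod(eig$vectors, W)
    ld <- determinant(crossprod(W), logarithm = TRUE)$modulus[1]
    for (lambda in c(0.01, 0.5, 3, 40)) {
      expect_equal(
        archwalk:::lmm_profile_loglik(lambda, yr, Wr, eig$values),
        dense_loglik(lambda, y, W, K), tolerance = 1e-8)
      expect_equal(
        archwalk:::lmm_profile_loglik(lambda, yr, Wr, eig$values,
                                      reml = TRUE, logdet_WtW = ld),
        dense_loglik(lambda, y, W, K, reml = TRUE), tolerance = 1e-8)
    }
  }
})

test_that("null fit: pve limits and invariances", {
  # kinship with realistic relatedness structure (bottlenecked selfers)
  cfg <- sim_config(N = 150, N_bottleneck = 100, t_shift = 150,
                    generations = 250, L = 5e4, regime = "shifted_optimum",
                    opt0 = 0, opt1 = -15, omega = 6, n_sample = 100,
                    seed = 77)
  g <- simulate_population(cfg)$geno
  n <- nrow(g)
  K <- centered_kinship(g)
  # pure genetic signal: y drawn with sigma_e ~ 0 -> pve ~ 1
  set.seed(7)
  L <- chol(K + 1e-8 * diag(n))
  y <- drop(t(L) %*% rnorm(n))
  names(y) <- rownames(g)
  fit <- fit_null_lmm(y, K)
  expect_gte(fit$pve, 0.99)
  expect_s3_class(fit, "archwalk_lmm")
  expect_output(print(fit), "PVE")

  # independent noise -> pve near zero on average
  pves <- vapply(1:8, function(s) {
    set.seed(s)
    yn <- setNames(rnorm(n), rownames(g))
    fit_null_lmm(yn, K)$pve
  }, numeric(1))
  expect_lt(mean(pves), 0.15)

  # pve invariant to shifting and rescaling the phenotype
  f1 <- fit_null_lmm(y, K)
  f2 <- fit_null_lmm(y * 3.7 + 11, K)
  expect_equal(f1$pve, f2$pve, tolerance = 1e-5)

  expect_error(fit_null_lmm(setNames(rep(1, n), rownames(g)), K),
               "zero variance")
})

test_that("association reduces to OLS with K = cI and matches dense GLS", {
  # spec toy: intercept-only, y = 1:4, x = (0,0,1,1) -> beta = 2 exactly
  g <- genotype_matrix(matrix(c(0, 0, 1, 1), 4, 1),
                       line_ids = letters[1:4], variant_ids = "v1")
  K <- diag(4); dimnames(K) <- list(letters[1:4], letters[1:4])
  y <- setNames(as.numeric(1:4), letters[1:4])
  a <- assoc_scan(y, g, K, maf_min = 0)
  expect_equal(a$beta, 2)
  # LRT p equals the OLS likelihood-ratio p computed from RSS directly
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(residuals(lm(y ~ g[, 1]))^2)
  stat <- 4 * log(rss0 / rss1)
  expect_equal(a$p_lrt, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-6)

  # K = cI scaling leaves beta identical to OLS
  K5 <- 5 * K
  a5 <- assoc_scan(y, g, K5, maf_min = 0)
  expect_equal(a5$beta, 2)

  # duplicated variant columns give identical results
  g2 <- cbind(g, g)
  colnames(g2) <- c("v1", "v2")
  a2 <- assoc_scan(y, genotype_matrix(g2), K, maf_min = 0)
  expect_equal(a2$beta[1], a2$beta[2])
  expect_equal(a2$p_lrt[1], a2$p_lrt[2])
})

test_that("GLS effect estimates match the dense oracle at fixed lambda", {
  set.seed(21)
  n <- 5
  g <- random_geno(n, 12, seed = 77)
  K <- centered_kinship(g)
  y <- rnorm(n)
  x <- g[, which(apply(g, 2, var) > 0)[1]]
  W <- cbind(intercept = rep(1, n), x = x)
  eig <- eigen(K, symmetric = TRUE)
  yr <- drop(crossprod(eig$vectors, y))
  Wr <- crossprod(eig$vectors, W)
  for (lambda in c(0.1, 1, 10)) {
    ours <- archwalk:::lmm_gls(lambda, yr, Wr, eig$values)$coef
    expect_equal(unname(ours), unname(dense_gls(lambda, y, W, K)),
                 tolerance = 1e-8)
  }
})

test_that("scan flags covariate, monomorphic, low-MAF and collinear variants", {
  set.seed(3)
  n <- 30
  g <- random_geno(n, 6, seed = 8)
  g[, 2] <- 0                      # monomorphic
  g[, 3] <- c(1, rep(0, n - 1))    # maf 1/30 < 0.05
  g[, 4] <- g[, 1]                 # collinear with covariate variant 1
  g <- genotype_matrix(g)
  K <- centered_kinship(g)
  y <- setNames(rnorm(n) + g[, 1], rownames(g))
  a <- assoc_scan(y, g, K, covariate_variants = "v001")
  expect_equal(a$flag[1], "covariate")
  expect_true(is.na(a$p_lrt[1]))
  expect_equal(a$flag[2], "monomorphic")
  expect_equal(a$flag[3], "maf")
  expect_equal(a$flag[4], "collinear")
  expect_true(all(a$flag[5:6] == "" & !is.na(a$p_lrt[5:6])))
  expect_true(all(a$p_lrt[5:6] > 0 & a$p_lrt[5:6] <= 1))
})

test_that("null p-values are approximately uniform under permutation", {
  set.seed(99)
  n <- 80; m <- 1200
  X <- matrix(rbinom(n * m, 1, 0.4), n, m,
              dimnames = list(sprintf("l%02d", 1:n), sprintf("v%04d", 1:m)))
  g <- genotype_matrix(X)
  K <- centered_kinship(g)
  y <- setNames(sample(rnorm(n)), rownames(g))  # permuted, no signal
  a <- assoc_scan(y, g, K)
  p <- a$p_lrt[!is.na(a$p_lrt)]
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("broad-sense heritability: exact toy, perfect lines, noise floor", {
  # balanced 2x2 toy: A = {1,3}, B = {5,7} -> sigma_line 7, sigma_res 2
  p <- data.frame(line = c("A", "A", "B", "B"), rep = c(1, 2, 1, 2),
                  block = "B1", flowering_days = c(1, 3, 5, 7),
                  seed_count = NA_real_)
  expect_equal(broad_sense_h2(p), 7 / 9, tolerance = 1e-6)

  # identical replicates within lines -> H2 = 1
  p2 <- data.frame(line = rep(c("A", "B", "C"), each = 2), rep = c(1, 2),
                   block = "B1", flowering_days = rep(c(3, 9, 6), each = 2),
                   seed_count = NA_real_)
  expect_equal(broad_sense_h2(p2), 1, tolerance = 1e-6)

  # pure noise -> H2 near zero on average
  h2s <- vapply(1:10, function(s) {
    set.seed(s)
    pn <- data.frame(line = rep(sprintf("l%02d", 1:30), each = 4),
                     rep = 1:4, block = rep(c("B1", "B2", "B3", "B4"), 30),
                     flowering_days = rnorm(120, mean = 50),
                     seed_count = NA_real_)
    broad_sense_h2(pn)
  }, numeric(1))
  expect_lt(mean(h2s), 0.1)

  # all lines single replicate -> error
  p3 <- data.frame(line = c("A", "B"), rep = 1, block = "B1",
                   flowering_days = c(1, 2), seed_count = NA_real_)
  expect_error(broad_sense_h2(p3), "two or more replicates")
})
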