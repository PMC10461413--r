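test_that("Lindley scores follow the recurrence on hand examples", {
  a <- data.frame(id = c("a", "b", "c"), chrom = "1", pos = c(10, 20, 30),
                  p_lrt = c(1e-3, 1e-1, 1e-4))
  tr <- lindley_scores(a, xi = 2)[["1"]]
  expect_equal(tr$s, c(1, -1, 2))
  expect_equal(tr$L, c(1, 0, 2))

  a2 <- data.frame(id = letters[1:4], chrom = "1", pos = 1:4, p_lrt = 1)
  expect_equal(lindley_scores(a2, xi = 2)[["1"]]$L, rep(0, 4))

  a3 <- data.frame(id = "a", chrom = "1", pos = 1, p_lrt = 0)
  expect_warning(tr3 <- lindley_scores(a3, xi = 2), "clamped")
  expect_true(is.finite(tr3[["1"]]$L))
})

test_that("Lindley recurrence equals the O(n^2) suffix-sum oracle", {
  for (s in 1:25) {
    set.seed(s)
    sc <- rnorm(60, mean = -0.3)
    expect_equal(archwalk:::lindley(sc), lindley_oracle(sc),
                 tolerance = 1e-12)
  }
})

test_that("resampling threshold: quantile definition, monotonicity, determinism", {
  t1 <- significance_threshold(100, xi = 2, alpha = 0.05,
                               n_resample = 400, seed = 5)
  t2 <- significance_threshold(100, xi = 2, alpha = 0.05,
                               n_resample = 400, seed = 5)
  expect_identical(t1, t2)

  # alpha = 1 -> minimum of the resampled maxima
  set.seed(9)
  tmin <- significance_threshold(50, xi = 2, alpha = 1,
                                 n_resample = 300, seed = 9)
  expect_gte(tmin, 0)

  # non-increasing in alpha, non-decreasing in m (fixed seed)
  th_a <- vapply(c(0.01, 0.05, 0.2, 0.5),
                 function(a) significance_threshold(200, 2, a, 600, seed = 3),
                 numeric(1))
  expect_true(all(diff(th_a) <= 0))
  th_m <- vapply(c(50, 200, 800),
                 function(m) significance_threshold(m, 2, 0.05, 600, seed = 3),
                 numeric(1))
  expect_true(all(diff(th_m) >= 0))

  expect_error(significance_threshold(100, xi = 0.3), "xi must exceed")
})

test_that("zone calling respects reset boundaries, threshold, tie rule", {
  tr <- data.frame(id = letters[1:6], pos = (1:6) * 10,
                   p = NA, s = NA, L = c(0, 1, 3, 1, 0, 2))
  z <- call_zones(tr, threshold = 2.5, chrom = "1")
  expect_equal(nrow(z), 1L)
  expect_equal(z$start_idx, 2L)
  expect_equal(z$end_idx, 4L)
  expect_equal(z$peak_score, 3)
  expect_equal(z$peak_id, "c")

  expect_equal(nrow(call_zones(tr, threshold = 10)), 0L)

  tr2 <- data.frame(id = letters[1:7], pos = (1:7) * 10,
                    p = NA, s = NA, L = c(3, 1, 0, 0, 4, 2, 0))
  z2 <- call_zones(tr2, threshold = 2.5, chrom = "1")
  expect_equal(nrow(z2), 2L)  # two separated excursions

  # leftmost peak on ties
  tr3 <- data.frame(id = letters[1:4], pos = (1:4) * 10,
                    p = NA, s = NA, L = c(0, 3, 3, 1))
  expect_equal(call_zones(tr3, 2, chrom = "1")$peak_id, "b")
})

test_that("pairwise r2 matches hand values and handles degenerate input", {
  g <- genotype_matrix(
    matrix(c(0, 0, 1, 1,  0, 1, 0, 1,  0, 1, 1, 1,  0, 0, 1, 1), 4, 4),
    line_ids = letters[1:4], variant_ids = c("w", "x", "y", "z"))
  expect_equal(pairwise_r2(g, "w", "w"), 1)
  expect_equal(pairwise_r2(g, "w", "x"), 0)
  expect_equal(pairwise_r2(g, "y", "z"), 1 / 3)
  gna <- g; gna[, 1] <- c(NA, NA, NA, 1)
  expect_true(is.na(pairwise_r2(genotype_matrix(gna), 1, 2)))
})

test_that("clumping follows the greedy rule on the three-variant example", {
  # A best p; B in LD within window; C independent but significant
  g <- genotype_matrix(cbind(
    A = c(0, 0, 0, 1, 1, 1, 0, 1),
    B = c(0, 0, 0, 1, 1, 1, 0, 1),     # r2 = 1 with A
    C = c(1, 0, 1, 0, 0, 1, 0, 1)),
    line_ids = sprintf("l%d", 1:8))
  a <- data.frame(id = c("A", "B", "C"), chrom = "1",
                  pos = c(1e5, 1.5e5, 5e5),
                  p_lrt = c(1e-6, 1e-3, 5e-3))
  cl <- clump(a, g, p1 = 0.01, window_kb = 1000, r2 = 0.8)
  expect_equal(cl$n_clumps, 2L)
  expect_equal(cl$clumps[[1]]$index, "A")
  expect_equal(cl$clumps[[1]]$members, "B")
  expect_equal(cl$clumps[[2]]$index, "C")

  # moving B out of the window splits it off despite high r2
  a2 <- a; a2$pos[2] <- 1e5 + 1.5e6
  cl2 <- clump(a2, g, p1 = 0.01, window_kb = 1000, r2 = 0.8)
  expect_equal(cl2$n_clumps, 3L)

  # nothing below p1 -> empty
  a3 <- a; a3$p_lrt <- c(0.5, 0.2, 0.9)
  expect_equal(clump(a3, g)$n_clumps, 0L)
})

test_that("clumping matches the exhaustive oracle on random instances", {
  for (s in 1:6) {
    set.seed(s)
    m <- 40
    g <- random_geno(25, m, seed = s + 300)
    a <- data.frame(id = colnames(g), chrom = "1",
                    pos = sort(sample.int(2e6, m)),
                    p_lrt = runif(m)^3)
    cl <- clump(a, g, p1 = 0.05, window_kb = 500, r2 = 0.5)
    oracle <- clump_oracle(a, g, p1 = 0.05, window_kb = 500, r2 = 0.5)
    expect_equal(length(cl$clumps), length(oracle))
    got <- setNames(lapply(cl$clumps, function(x) sort(x$members)),
                    vapply(cl$clumps, `[[`, character(1), "index"))
    expect_equal(got[order(names(got))],
                 lapply(oracle, sort)[order(names(oracle))])
    # partition property: no variant in two clumps
    all_ids <- c(names(got), unlist(got))
    expect_false(anyDuplicated(all_ids) > 0)
  }
})

test_that("LD pruning: trivial cases and oracle agreement", {
  g <- random_geno(30, 10, seed = 12)
  # duplicate adjacent columns: exactly one survives
  g2 <- g; g2[, 5] <- g2[, 4]
  g2 <- genotype_matrix(g2)
  kept <- ld_prune(g2, window = 10, step = 5, r2 = 0.99)
  expect_true(xor("v004" %in% kept, "v005" %in% kept))

  # mutually independent variants are all retained
  set.seed(8)
  gi <- genotype_matrix(matrix(rbinom(200 * 8, 1, 0.5), 200, 8,
                               dimnames = list(sprintf("l%03d", 1:200),
                                               sprintf("v%03d", 1:8))))
  expect_equal(length(ld_prune(gi, r2 = 0.3)), 8L)

  for (s in 1:6) {
    g3 <- random_geno(20, 30, seed = s + 900)
    expect_equal(ld_prune(g3, window = 8, step = 3, r2 = 0.4),
                 ld_prune_oracle(g3, window = 8, step = 3, r2 = 0.4))
  }

  # no retained pair within a window exceeds the threshold
  g4 <- random_geno(15, 25, seed = 5)
  kept4 <- ld_prune(g4, window = 6, step = 2, r2 = 0.5)
  idx <- match(kept4, colnames(g4))
  for (w in seq(1, length(idx) - 1)) {
    in_win <- idx[idx >= idx[w] & idx < idx[w] + 6]
    if (length(in_win) >= 2) {
      combs <- utils::combn(in_win, 2)
      for (k in seq_len(ncol(combs))) {
        rr <- pairwise_r2(g4, combs[1, k], combs[2, k])
        if (!is.na(rr)) expect_lte(rr, 0.5)
      }
    }
  }
})

test_that("representative loci: argmin peak, LD thinning, manual append", {
  g <- genotype_matrix(cbind(
    a = c(0, 1, 0, 1, 0, 1),
    b = c(1, 1, 0, 0, 1, 0),
    c = c(1, 1, 0, 0, 0, 1),
    d = c(0, 1, 1, 0, 1, 0)),
    line_ids = sprintf("l%d", 1:6))
  assoc <- data.frame(id = c("a", "b", "c", "d"), chrom = "1",
                      pos = c(10, 20, 30, 40),
                      beta = c(1, -2, 3, 0.5),
                      p_lrt = c(1e-4, 1e-7, 1e-3, 1e-5))
  tracks <- list("1" = data.frame(id = assoc$id, pos = assoc$pos,
                                  p = assoc$p_lrt, s = 1,
                                  L = c(1, 2, 1, 3)))
  zones <- data.frame(chrom = "1", start_idx = 1L, end_idx = 3L,
                      start_bp = 10, end_bp = 30, peak_score = 2,
                      peak_id = "b", peak_idx = 2L)
  loci <- representative_loci(zones, tracks, assoc, g)
  expect_equal(loci$id, "b")  # smallest p within the zone

  # two zones whose representatives are in strong LD: weaker p dropped
  g2 <- g; g2[, "c"] <- g2[, "b"]
  g2 <- genotype_matrix(g2)
  zones2 <- rbind(zones,
                  data.frame(chrom = "1", start_idx = 3L, end_idx = 4L,
                             start_bp = 30, end_bp = 40, peak_score = 3,
                             peak_id = "c", peak_idx = 3L))
  assoc2 <- assoc
  assoc2$p_lrt <- c(1e-4, 1e-7, 1e-6, 0.5)  # zone 2 rep = c
  loci2 <- representative_loci(zones2, tracks, assoc2, g2, r2max = 0.5)
  expect_equal(loci2$id, "b")  # c removed (r2 = 1, larger p)

  # manual fixed locus is appended and flagged
  man <- data.frame(id = "flc_like", chrom = "1", pos = 999, beta = -9,
                    daf = 1, impact = "HIGH")
  loci3 <- representative_loci(zones, tracks, assoc, g, manual = man)
  expect_true("flc_like" %in% loci3$id)
  expect_true(loci3$fixed[loci3$id == "flc_like"])
})
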