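# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths (dense matrix algebra instead of the
# eigen trick, O(n^2) scans instead of recurrences, exhaustive enumeration
# instead of greedy bookkeeping).

# Dense ML / REML log-likelihood of y = W a + u + e with V = s2 (lambda K + I)
dense_loglik <- function(lambda, y, W, K, reml = FALSE) {
  n <- length(y)
  p <- ncol(W)
  V <- lambda * K + diag(n)
  Vi <- solve(V)
  A <- t(W) %*% Vi %*% W
  alpha <- solve(A, t(W) %*% Vi %*% y)
  r <- y - W %*% alpha
  rss <- drop(t(r) %*% Vi %*% r)
  ldV <- determinant(V, logarithm = TRUE)$modulus[1]
  if (reml) {
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + ldV +
              determinant(A, logarithm = TRUE)$modulus[1] -
              determinant(t(W) %*% W, logarithm = TRUE)$modulus[1] + (n - p))
  } else {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + ldV + n)
  }
}

# Dense GLS coefficients at fixed lambda
dense_gls <- function(lambda, y, W, K) {
  V <- lambda * K + diag(length(y))
  Vi <- solve(V)
  drop(solve(t(W) %*% Vi %*% W, t(W) %*% Vi %*% y))
}

# O(n^2) local-score oracle: L_i = max(0, max_j sum(s[j..i]))
lindley_oracle <- function(s) {
  n <- length(s)
  L <- numeric(n)
  for (i in seq_len(n)) {
    best <- 0
    for (j in seq_len(i)) {
      ss <- sum(s[j:i])
      if (ss > best) best <- ss
    }
    L[i] <- best
  }
  L
}

# Exhaustive clump oracle following the stated rule literally
clump_oracle <- function(assoc, geno, p1 = 0.01, window_kb = 1000, r2 = 0.8) {
  a <- assoc[!is.na(assoc$p_lrt) & assoc$p_lrt < p1, , drop = FALSE]
  a <- a[order(a$p_lrt, a$chrom, a$pos), , drop = FALSE]
  assigned <- character()
  clumps <- list()
  while (nrow(a)) {
    idx <- a[1, ]
    a <- a[-1, , drop = FALSE]
    if (idx$id %in% assigned) next
    assigned <- c(assigned, idx$id)
    members <- character()
    for (k in seq_len(nrow(a))) {
      cand <- a[k, ]
      if (cand$id %in% assigned) next
      if (cand$chrom != idx$chrom) next
      if (abs(cand$pos - idx$pos) > window_kb * 1000) next
      rr <- suppressWarnings(cor(geno[, idx$id], geno[, cand$id],
                                 use = "pairwise.complete.obs")^2)
      if (!is.na(rr) && rr > r2) {
        members <- c(members, cand$id)
        assigned <- c(assigned, cand$id)
      }
    }
    clumps[[idx$id]] <- members
  }
  clumps
}

# Literal sliding-window prune oracle
ld_prune_oracle <- function(geno, window = 50, step = 10, r2 = 0.3) {
  m <- ncol(geno)
  keep <- rep(TRUE, m)
  starts <- seq(1L, max(1L, m), by = step)
  for (st in starts) {
    en <- min(m, st + window - 1L)
    repeat {
      act <- (st:en)[keep[st:en]]
      hit <- NULL
      if (length(act) >= 2) {
        for (ii in seq_len(length(act) - 1)) {
          for (jj in (ii + 1):length(act)) {
            rr <- suppressWarnings(cor(geno[, act[ii]], geno[, act[jj]],
                                       use = "pairwise.complete.obs")^2)
            if (!is.na(rr) && rr > r2) { hit <- act[jj]; break }
          }
          if (!is.null(hit)) break
        }
      }
      if (is.null(hit)) break
      keep[hit] <- FALSE
    }
    if (en == m) break
  }
  colnames(geno)[keep]
}

# Random small genotype fixture (lines x variants over {0,1} with optional NA)
random_geno <- function(n, m, miss = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rbinom(n * m, 1, runif(m, 0.15, 0.85)[rep(seq_len(m), each = n)]),
              n, m)
  if (miss > 0) x[runif(n * m) < miss] <- NA
  genotype_matrix(x, line_ids = sprintf("l%02d", seq_len(n)),
                  variant_ids = sprintf("v%03d", seq_len(m)))
}

# Hand-written toy VCF text
toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "va", "A", "T", ".", ".", "AA=A", "GT",
          "0/0", "1/1", "0/1", sep = "\t"),
    paste("1", "200", "vb", "C", "G", ".", ".", "AA=G", "GT",
          "0/0", "1/1", "./.", sep = "\t"),
    paste("1", "300", "vc", "G", "A", ".", ".", "AA=N", "GT",
          "1/1", "0/0", "1/1", sep = "\t"),
    paste("1", "400", "vd", "T", "C", ".", ".", "AA=T;IMPACT=HIGH", "GT",
          "0/0", "0/0", "1/1", sep = "\t"),
    paste("2", "50", "ve", "A", "C,G", ".", ".", "AA=A", "GT",
          "0/0", "1/1", "2/2", sep = "\t")
  ), path)
  path
}
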