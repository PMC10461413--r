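#' Centered kinship matrix from a dosage matrix
#'
#' \eqn{K = (1/m) \sum_j (x_j - \bar x_j 1)(x_j - \bar x_j 1)^T} over the m
#' polymorphic variants; missing dosages are mean-imputed per variant
#' (only here -- stored matrices are never imputed). Monomorphic variants
#' are skipped.
#'
#' @param geno genotype matrix (lines x variants).
#' @return symmetric n x n kinship matrix with line ordering preserved.
#' @export
centered_kinship <- function(geno) {
  if (nrow(geno) < 2) stop("need at least two lines")
  X <- impute_mean(geno)
  keep <- apply(X, 2, function(v) var(v) > 0)
  if (!any(keep)) stop("no polymorphic variants")
  X <- X[, keep, drop = FALSE]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  K <- tcrossprod(Xc) / ncol(Xc)
  dimnames(K) <- list(rownames(geno), rownames(geno))
  K
}

impute_mean <- function(geno) {
  nas <- which(is.na(geno))
  if (!length(nas)) return(geno)
  means <- colMeans(geno, na.rm = TRUE)
  means[is.nan(means)] <- 0
  idx <- arrayInd(nas, dim(geno))
  geno[nas] <- means[idx[, 2]]
  geno
}

# Profile (restricted) log-likelihood of lambda = sigma_g^2/sigma_e^2 for
# y = W alpha + u + e, u ~ (0, sigma_g^2 K), via the eigendecomposition of K.
# yr, Wr are U'y, U'W; d_eig the eigenvalues of K.
lmm_profile_loglik <- function(lambda, yr, Wr, d_eig, reml = FALSE,
                               logdet_WtW = NULL) {
  n <- length(yr)
  p <- ncol(Wr)
  d <- lambda * d_eig + 1
  if (any(d <= 0)) return(-Inf)
  Wd <- Wr / d
  A <- crossprod(Wr, Wd)
  alpha <- tryCatch(solve(A, crossprod(Wd, yr)), error = function(e) NULL)
  if (is.null(alpha)) return(-Inf)
  r <- yr - Wr %*% alpha
  rss <- sum(r * r / d)
  if (rss <= 0) return(-Inf)
  if (reml) {
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(d)) +
              determinant(A, logarithm = TRUE)$modulus[1] -
              logdet_WtW + (n - p))
  } else {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n)
  }
}

# maximize profile loglik over lambda on a log10 grid + golden refinement
optimize_lambda <- function(yr, Wr, d_eig, reml = FALSE,
                            bounds = c(1e-5, 1e5), n_grid = 100) {
  logdet_WtW <- determinant(crossprod(Wr), logarithm = TRUE)$modulus[1]
  f <- function(l10) lmm_profile_loglik(10^l10, yr, Wr, d_eig, reml,
                                        logdet_WtW)
  grid <- seq(log10(bounds[1]), log10(bounds[2]), length.out = n_grid)
  ll <- vapply(grid, f, numeric(1))
  if (all(!is.finite(ll)))
    stop("non-finite likelihood over lambda in [", bounds[1], ", ",
         bounds[2], "]")
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  op <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (op$objective >= ll[i]) {
    list(lambda = 10^op$maximum, loglik = op$objective)
  } else {
    list(lambda = 10^grid[i], loglik = ll[i])
  }
}

# GLS estimates at a given lambda (rotated coordinates); returns coefficients,
# their covariance scale, and the ML sigma_e^2
lmm_gls <- function(lambda, yr, Wr, d_eig) {
  n <- length(yr)
  d <- lambda * d_eig + 1
  Wd <- Wr / d
  A <- crossprod(Wr, Wd)
  Ainv <- solve(A)
  alpha <- Ainv %*% crossprod(Wd, yr)
  r <- yr - Wr %*% alpha
  s2 <- sum(r * r / d) / n
  list(coef = drop(alpha), cov_unscaled = Ainv, sigma_e2 = s2)
}

#' Fit the null linear mixed model
#'
#' Restricted maximum likelihood for
#' \eqn{y = W\alpha + u + \epsilon,\ u \sim (0, \sigma_g^2 K),\
#' \epsilon \sim (0, \sigma_e^2 I)}, profiled over the variance ratio
#' \eqn{\lambda = \sigma_g^2/\sigma_e^2} using one eigendecomposition of K
#' and a 1-D search (log grid of 100 points on \eqn{[10^{-5}, 10^5]} plus
#' local refinement). The proportion of variance explained by relatedness is
#' \eqn{pve = \hat\lambda \bar k / (\hat\lambda \bar k + 1)} with
#' \eqn{\bar k = tr(K)/n} (the kinship is not standardized).
#'
#' @param y named numeric phenotype vector (one value per line) or the
#'   data.frame returned by [median_phenotype()].
#' @param K kinship matrix with matching line names.
#' @param W covariate matrix including an intercept (default intercept only).
#' @param method `"reml"` (default) or `"ml"`.
#' @return object of class `archwalk_lmm` with elements `lambda_hat`,
#'   `sigma_g2`, `sigma_e2`, `loglik`, `pve`, `method`, `n`, `coef`.
#' @export
fit_null_lmm <- function(y, K, W = NULL, method = c("reml", "ml")) {
  method <- match.arg(method)
  y <- as_line_vector(y)
  ord <- match(names(y), rownames(K))
  if (anyNA(ord)) stop("phenotype lines missing from kinship: ",
                       paste(utils::head(names(y)[is.na(ord)], 3),
                             collapse = ", "))
  K <- K[ord, ord, drop = FALSE]
  n <- length(y)
  if (var(y) == 0) stop("phenotype has zero variance")
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (qr(W)$rank < ncol(W)) stop("covariate matrix is rank deficient")
  eig <- eigen(K, symmetric = TRUE)
  yr <- drop(crossprod(eig$vectors, y))
  Wr <- crossprod(eig$vectors, W)
  opt <- optimize_lambda(yr, Wr, eig$values, reml = (method == "reml"))
  gls <- lmm_gls(opt$lambda, yr, Wr, eig$values)
  kbar <- mean(diag(K))
  pve <- opt$lambda * kbar / (opt$lambda * kbar + 1)
  structure(list(lambda_hat = opt$lambda,
                 sigma_e2 = gls$sigma_e2,
                 sigma_g2 = opt$lambda * gls$sigma_e2,
                 loglik = opt$loglik, pve = pve, method = method,
                 n = n, coef = gls$coef,
                 eigen = eig, yr = yr, Wr = Wr, W = W, y = y),
            class = "archwalk_lmm")
}

as_line_vector <- function(y) {
  if (is.data.frame(y)) {
    if (!all(c("line", "flowering_days") %in% names(y)))
      stop("data.frame phenotype needs columns line and flowering_days")
    y <- setNames(y$flowering_days, y$line)
  }
  if (is.null(names(y))) stop("phenotype vector must be named by line")
  y <- y[!is.na(y)]
  y
}

#' @method print archwalk_lmm
#' @export
print.archwalk_lmm <- function(x, ...) {
  cat("Linear mixed model (", toupper(x$method), "), n = ", x$n, " lines\n",
      sep = "")
  cat(sprintf("  lambda = sigma_g^2/sigma_e^2 : %.4g\n", x$lambda_hat))
  cat(sprintf("  sigma_g^2 : %.4g   sigma_e^2 : %.4g\n",
              x$sigma_g2, x$sigma_e2))
  cat(sprintf("  PVE (variance explained by relatedness) : %.3f\n", x$pve))
  cat(sprintf("  log-likelihood : %.4f\n", x$loglik))
  invisible(x)
}

#' @method logLik archwalk_lmm
#' @export
logLik.archwalk_lmm <- function(object, ...) {
  structure(object$loglik, df = ncol(object$Wr) + 2, class = "logLik")
}

#' @method coef archwalk_lmm
#' @export
coef.archwalk_lmm <- function(object, ...) object$coef

#' Univariate mixed-model association scan
#'
#' For each variant, fits \eqn{y = W\alpha + x\beta + u + \epsilon} by
#' maximum likelihood (the variance ratio re-optimized per marker), and
#' tests \eqn{\beta = 0} with a 1-df likelihood-ratio test against the ML
#' null. Effects are reported per derived (or alt) allele in trait units.
#' Missing dosages are mean-imputed transiently inside the scan.
#' Monomorphic variants, variants below the minor-allele-frequency filter
#' and variants collinear with the covariates get `NA` results and a flag.
#'
#' @param y phenotype (named vector or [median_phenotype()] output).
#' @param geno genotype matrix; rows must cover the phenotyped lines.
#' @param K kinship matrix.
#' @param variants optional variant table supplying chrom/pos for output.
#' @param W covariate matrix incl. intercept (default intercept only).
#' @param covariate_variants ids of variants whose dosages are added to the
#'   covariates (their own tests return `NA`, flag `"covariate"`).
#' @param maf_min minor allele frequency filter (default 0.05).
#' @param per_marker_lambda re-optimize lambda per marker (default TRUE);
#'   FALSE fixes it at the null ML estimate (faster, slightly conservative).
#' @return data.frame: `id`, `chrom`, `pos`, `n_used`, `maf`, `beta`, `se`,
#'   `p_lrt`, `flag`.
#' @export
assoc_scan <- function(y, geno, K, variants = NULL, W = NULL,
                       covariate_variants = NULL, maf_min = 0.05,
                       per_marker_lambda = TRUE) {
  y <- as_line_vector(y)
  common <- intersect(names(y), rownames(geno))
  if (!length(common)) stop("no lines shared between phenotype and genotypes")
  y <- y[common]
  geno <- geno[common, , drop = FALSE]
  K <- K[common, common, drop = FALSE]
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))

  if (length(covariate_variants)) {
    missing_cov <- setdiff(covariate_variants, colnames(geno))
    if (length(missing_cov))
      stop("covariate variant(s) not in genotypes: ",
           paste(missing_cov, collapse = ", "))
    Xc <- impute_mean(geno[, covariate_variants, drop = FALSE])
    W <- cbind(W, Xc)
  }
  if (qr(W)$rank < ncol(W)) stop("covariate matrix is rank deficient")

  eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  d_eig <- eig$values
  yr <- drop(crossprod(U, y))
  Wr <- crossprod(U, W)
  null_fit <- optimize_lambda(yr, Wr, d_eig, reml = FALSE)
  l0 <- null_fit$loglik

  Ximp <- impute_mean(geno)
  Xr <- crossprod(U, Ximp)

  m <- ncol(geno)
  beta <- se <- p <- maf <- rep(NA_real_, m)
  n_used <- integer(m)
  flag <- rep("", m)
  # collinearity screen: residual variance of x after projecting on W
  Wqr <- qr(W)
  for (j in seq_len(m)) {
    xj <- geno[, j]
    obs <- !is.na(xj)
    n_used[j] <- sum(obs)
    f <- mean(xj[obs])
    maf[j] <- min(f, 1 - f)
    if (colnames(geno)[j] %in% covariate_variants) {
      flag[j] <- "covariate"
      next
    }
    if (is.nan(maf[j]) || maf[j] <= 0) {
      flag[j] <- "monomorphic"
      next
    }
    if (maf[j] < maf_min) {
      flag[j] <- "maf"
      next
    }
    resid_x <- qr.resid(Wqr, Ximp[, j])
    if (var(resid_x) < 1e-12) {
      flag[j] <- "collinear"
      next
    }
    Wx <- cbind(Wr, Xr[, j])
    if (per_marker_lambda) {
      alt <- optimize_lambda(yr, Wx, d_eig, reml = FALSE, n_grid = 20)
    } else {
      alt <- list(lambda = null_fit$lambda,
                  loglik = lmm_profile_loglik(null_fit$lambda, yr, Wx, d_eig))
    }
    gls <- lmm_gls(alt$lambda, yr, Wx, d_eig)
    k <- ncol(Wx)
    beta[j] <- gls$coef[k]
    se[j] <- sqrt(gls$sigma_e2 * gls$cov_unscaled[k, k])
    stat <- max(0, 2 * (alt$loglik - l0))
    p[j] <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  out <- data.frame(id = colnames(geno), chrom = NA_character_,
                    pos = NA_integer_, n_used = n_used, maf = maf,
                    beta = beta, se = se, p_lrt = p, flag = flag,
                    stringsAsFactors = FALSE)
  if (!is.null(variants)) {
    idx <- match(out$id, variants$id)
    out$chrom <- variants$chrom[idx]
    out$pos <- variants$pos[idx]
  }
  out
}

#' Broad-sense heritability from replicated phenotypes
#'
#' Fits flowering time on block (fixed) plus line (random intercept) by
#' restricted maximum likelihood with [lme4::lmer()] and returns
#' \eqn{H^2 = \sigma^2_{line} / (\sigma^2_{line} + \sigma^2_{res})}.
#' For balanced designs this agrees with the one-way ANOVA
#' method-of-moments closed form.
#'
#' @param pheno replicate-level phenotype table.
#' @param trait column to analyse (default `"flowering_days"`).
#' @return H-squared in \[0, 1\].
#' @export
broad_sense_h2 <- function(pheno, trait = "flowering_days") {
  validate_phenotypes(pheno)
  pheno <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  reps_per_line <- table(pheno$line)
  if (all(reps_per_line < 2))
    stop("no line has two or more replicates")
  if (length(reps_per_line) < 2)
    stop("need at least two lines")
  pheno$..y <- pheno[[trait]]
  form <- if (length(unique(pheno$block)) > 1)
    ..y ~ block + (1 | line) else ..y ~ (1 | line)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = pheno, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_line <- vc$vcov[vc$grp == "line"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  v_line / (v_line + v_res)
}
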