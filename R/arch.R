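#' Exponential vs uniform fit of an effect-size distribution
#'
#' Maximum-likelihood fit of two one-parameter families to absolute effect
#' sizes: exponential with rate \eqn{\hat\lambda = 1/\bar x}
#' (log-likelihood \eqn{n(\ln\hat\lambda - 1)}), and uniform on
#' \eqn{(0, \hat\theta]} with \eqn{\hat\theta = \max x}
#' (log-likelihood \eqn{-n \ln\hat\theta}). Models are compared by AIC with
#' k = 1 each; under strong directional selection (an adaptive walk) the
#' exponential is expected to win, under stabilizing selection the uniform.
#'
#' @param abs_beta positive absolute effect sizes (days).
#' @param theta_unbiased use the unbiased \eqn{(n+1)/n \cdot \max} upper
#'   bound instead of the MLE (default FALSE; the MLE is the documented
#'   convention).
#' @return object of class `effdist_fit`: `n`, `lambda_hat`, `theta_hat`,
#'   `loglik_exp`, `loglik_unif`, `aic_exp`, `aic_unif`, `chosen`
#'   (`"exponential"` or `"uniform"`; AIC ties go to uniform with
#'   `tie = TRUE`).
#' @export
fit_effect_distributions <- function(abs_beta, theta_unbiased = FALSE) {
  x <- abs_beta[!is.na(abs_beta)]
  n <- length(x)
  if (n < 1) stop("need at least one effect size")
  if (any(x <= 0)) stop("effect sizes must be positive; pass |beta|")
  lambda_hat <- 1 / mean(x)
  theta_hat <- if (theta_unbiased) (n + 1) / n * max(x) else max(x)
  loglik_exp <- n * (log(lambda_hat) - 1)
  loglik_unif <- -n * log(theta_hat)
  aic_exp <- 2 - 2 * loglik_exp
  aic_unif <- 2 - 2 * loglik_unif
  chosen <- if (aic_exp < aic_unif) "exponential" else "uniform"
  structure(list(n = n, lambda_hat = lambda_hat, theta_hat = theta_hat,
                 loglik_exp = loglik_exp, loglik_unif = loglik_unif,
                 aic_exp = aic_exp, aic_unif = aic_unif, chosen = chosen,
                 tie = aic_exp == aic_unif),
            class = "effdist_fit")
}

#' @method print effdist_fit
#' @export
print.effdist_fit <- function(x, ...) {
  cat("Effect-size distribution fit (n =", x$n, "loci)\n")
  cat(sprintf("  exponential: rate = %.4g  logLik = %.4f  AIC = %.2f\n",
              x$lambda_hat, x$loglik_exp, x$aic_exp))
  cat(sprintf("  uniform(0, theta]: theta = %.4g  logLik = %.4f  AIC = %.2f\n",
              x$theta_hat, x$loglik_unif, x$aic_unif))
  cat("  chosen:", x$chosen, if (x$tie) "(AIC tie)" else "", "\n")
  invisible(x)
}

#' @method coef effdist_fit
#' @export
coef.effdist_fit <- function(object, ...) {
  c(lambda_hat = object$lambda_hat, theta_hat = object$theta_hat)
}

#' @method AIC effdist_fit
#' @export
AIC.effdist_fit <- function(object, ..., k = 2) {
  c(exponential = object$aic_exp, uniform = object$aic_unif)
}

#' @method logLik effdist_fit
#' @export
logLik.effdist_fit <- function(object, ...) {
  ll <- if (object$chosen == "exponential") object$loglik_exp
        else object$loglik_unif
  structure(ll, df = 1, class = "logLik")
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U with midrank ties; exact enumeration when both
#' samples are small (`min(n1, n2) < 8` and no ties), otherwise the normal
#' approximation with tie correction. If all values are identical across
#' both samples, `p = 1`.
#'
#' @param x,y numeric samples.
#' @return list with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1)
    return(list(U = length(x) * length(y) / 2, p = 1))
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) < 8 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors, n >= 3, both nonconstant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) stop("inputs must be nonconstant")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Watterson's theta per site
#'
#' \eqn{\theta_W = S / (a_n L)} with \eqn{a_n = \sum_{i=1}^{n-1} 1/i}, for
#' S segregating sites in a sample of n sequences over L surveyed sites.
#'
#' @param S segregating site count.
#' @param n sample size (number of sequences).
#' @param L sites surveyed (default 1: per-locus theta).
#' @return theta_W per site.
#' @export
watterson_theta <- function(S, n, L = 1) {
  if (n < 2) stop("n must be >= 2")
  if (L < 1) stop("L must be >= 1")
  a_n <- sum(1 / seq_len(n - 1))
  S / (a_n * L)
}

#' Effective population size from diversity
#'
#' \eqn{N_e = \theta_W / (4\mu)} for a per-site diversity estimate and
#' per-site per-generation mutation rate.
#'
#' @param theta_per_site Watterson's theta per site.
#' @param mu mutation rate per site per generation (> 0).
#' @return N_e.
#' @export
ne_from_theta <- function(theta_per_site, mu) {
  if (mu <= 0) stop("mu must be > 0")
  theta_per_site / (4 * mu)
}

#' Neutral expectation of allele age from frequency
#'
#' Mean age, in generations, of a neutral derived allele observed at
#' frequency p in a population of effective size \eqn{N_e}:
#' \eqn{\bar t = -4 N_e\, p \ln(p) / (1 - p)}. This is a
#' neutral-expectation stand-in, not a genealogy-based age estimate; use an
#' external age table where one is available.
#'
#' @param p derived allele frequency strictly inside (0, 1).
#' @param N_e effective population size.
#' @return expected age in generations.
#' @export
expected_allele_age <- function(p, N_e) {
  if (any(p <= 0 | p >= 1))
    stop("p must be strictly inside (0, 1); fixed or absent alleles need ",
         "externally estimated ages")
  -4 * N_e * p * log(p) / (1 - p)
}

#' Assemble a per-population genetic-architecture report
#'
#' Collects, per population: polygenicity counts (significant zones and
#' clumps), replicate-based broad-sense heritability, LMM PVE, the
#' exponential-vs-uniform effect-size fit on locus representatives,
#' Mann-Whitney comparisons of |effect| between all population pairs, and
#' Pearson correlations of derived allele frequency against effect size
#' (overall and split by effect sign) and of allele age against frequency.
#'
#' @param populations named list; each element a list with components
#'   `loci` (representative-locus table from [representative_loci()]),
#'   `n_zones`, `n_clumps`, `h2`, `pve`, and optionally `ages` (named
#'   vector of allele ages for the loci) and `theta_w`, `N_e`.
#' @param include_fixed include manually appended fixed loci in the
#'   distribution fits (default TRUE, mirroring how fixed causal variants
#'   are added to the locus sets).
#' @return object of class `arch_report` (serializable with
#'   [write_report()]).
#' @export
assemble_report <- function(populations, include_fixed = TRUE) {
  per_pop <- lapply(names(populations), function(nm) {
    p <- populations[[nm]]
    loci <- p$loci
    if (!include_fixed && !is.null(loci$fixed))
      loci <- loci[!loci$fixed, , drop = FALSE]
    betas <- abs(loci$beta)
    betas <- betas[!is.na(betas) & betas > 0]
    fit <- if (length(betas) >= 1) fit_effect_distributions(betas) else NULL
    if (is.null(fit))
      message("population ", nm, ": <1 usable locus; distribution fit skipped")
    cors <- locus_correlations(loci, p$ages)
    list(population = nm, n_loci = nrow(loci), n_zones = p$n_zones,
         n_clumps = p$n_clumps, h2 = p$h2, pve = p$pve,
         effdist = fit, correlations = cors,
         theta_w = p$theta_w, N_e = p$N_e, abs_beta = betas)
  })
  names(per_pop) <- names(populations)

  pops <- names(per_pop)
  mw <- list()
  if (length(pops) >= 2) {
    for (i in seq_len(length(pops) - 1)) {
      for (j in (i + 1):length(pops)) {
        a <- per_pop[[pops[i]]]$abs_beta
        b <- per_pop[[pops[j]]]$abs_beta
        if (length(a) && length(b)) {
          t <- mann_whitney(a, b)
          mw[[paste(pops[i], pops[j], sep = "-")]] <-
            list(U = t$U, p = t$p, n1 = length(a), n2 = length(b))
        }
      }
    }
  }
  structure(list(populations = per_pop, mann_whitney = mw),
            class = "arch_report")
}

locus_correlations <- function(loci, ages = NULL) {
  out <- list()
  ok <- !is.na(loci$daf) & !is.na(loci$beta)
  try_cor <- function(x, y) {
    if (length(x) >= 3 && var(x) > 0 && var(y) > 0)
      pearson_cor(x, y)[c("r", "p", "n")] else NULL
  }
  out$daf_vs_beta <- try_cor(loci$daf[ok], loci$beta[ok])
  up <- ok & loci$beta > 0
  dn <- ok & loci$beta < 0
  out$daf_vs_beta_positive <- try_cor(loci$daf[up], loci$beta[up])
  out$daf_vs_beta_negative <- try_cor(loci$daf[dn], loci$beta[dn])
  if (!is.null(ages)) {
    a <- ages[loci$id]
    ok2 <- ok & !is.na(a)
    out$age_vs_daf <- try_cor(a[ok2], loci$daf[ok2])
  }
  out
}

#' @method print arch_report
#' @export
print.arch_report <- function(x, ...) {
  cat("Genetic-architecture report:", length(x$populations),
      "population(s)\n")
  for (p in x$populations) {
    cat(sprintf("  %s: %d loci, %d zones, %d clumps",
                p$population, p$n_loci,
                if (is.null(p$n_zones)) NA_integer_ else p$n_zones,
                if (is.null(p$n_clumps)) NA_integer_ else p$n_clumps))
    if (!is.null(p$h2)) cat(sprintf(", H2 = %.3f", p$h2))
    if (!is.null(p$pve)) cat(sprintf(", PVE = %.3f", p$pve))
    if (!is.null(p$effdist))
      cat(sprintf("; effect sizes favor %s (AIC %.2f vs %.2f)",
                  p$effdist$chosen, p$effdist$aic_exp, p$effdist$aic_unif))
    cat("\n")
  }
  for (nm in names(x$mann_whitney)) {
    t <- x$mann_whitney[[nm]]
    cat(sprintf("  MW |beta| %s: U = %.1f, p = %.4g\n", nm, t$U, t$p))
  }
  invisible(x)
}

#' Serialize / restore an architecture report as JSON
#'
#' @param report `arch_report` object.
#' @param path output JSON file.
#' @return `path` invisibly; `read_report()` returns the restored list.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  x$populations <- lapply(x$populations, function(p) {
    p$effdist <- if (!is.null(p$effdist)) unclass(p$effdist) else NULL
    p$abs_beta <- as.numeric(p$abs_beta)
    p
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  structure(x, class = "arch_report")
}
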