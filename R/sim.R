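#' Configuration for the forward Wright-Fisher simulator
#'
#' The simulator emulates, at desk scale, the contrast between a large,
#' long-established population under stabilizing selection and a small,
#' recently founded island population under strong directional selection
#' after an optimum shift. Individuals are diploid and reproduce with
#' partial self-fertilization; the quantitative trait is the sum of
#' additive mutation effects; fitness is Gaussian in the distance between
#' trait and optimum, \eqn{w(z) = \exp(-(z - opt)^2 / (2\omega^2))}.
#'
#' @param N diploid population size before any bottleneck.
#' @param N_bottleneck population size after the shift generation (0 = none).
#' @param t_shift generation at which the optimum moves `opt0 -> opt1` and
#'   the size drops to `N_bottleneck` (0 = never).
#' @param generations total generations to simulate.
#' @param L genome length in bp (single linear chromosome).
#' @param mu_per_site,rec_per_site mutation and crossover rates per site per
#'   gamete per generation.
#' @param selfing probability an offspring is produced by selfing.
#' @param p_null probability a new mutation has exactly zero trait effect.
#' @param sigma_effect standard deviation (trait units, days) of ordinary
#'   non-null mutation effects, drawn Normal(0, sigma_effect).
#' @param p_large probability a non-null mutation belongs to the rare
#'   large-effect (loss-of-function-like) class.
#' @param sigma_large standard deviation of the large-effect class.
#' @param n_founders size of the random colonist group that parents the
#'   first post-shift generation (0 disables the founder event).
#' @param regime `"neutral"`, `"stabilizing"` or `"shifted_optimum"`.
#' @param opt0,opt1 trait optima before/after the shift (days).
#' @param omega width of the Gaussian fitness function (days).
#' @param n_sample number of inbred accessions sampled at the end.
#' @param seed integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(N = 200, N_bottleneck = 0, t_shift = 0,
                       generations = 400, L = 1e5,
                       mu_per_site = 2.5e-6, rec_per_site = 3e-5,
                       selfing = 0.95, p_null = 0.9, sigma_effect = 1,
                       p_large = 0.05, sigma_large = 10, n_founders = 2,
                       regime = c("neutral", "stabilizing", "shifted_optimum"),
                       opt0 = 0, opt1 = -15, omega = 5,
                       n_sample = 50, seed = 1) {
  regime <- match.arg(regime)
  cfg <- list(N = as.integer(N), N_bottleneck = as.integer(N_bottleneck),
              t_shift = as.integer(t_shift),
              generations = as.integer(generations), L = as.integer(L),
              mu_per_site = mu_per_site, rec_per_site = rec_per_site,
              selfing = selfing, p_null = p_null,
              sigma_effect = sigma_effect, p_large = p_large,
              sigma_large = sigma_large,
              n_founders = as.integer(n_founders), regime = regime,
              opt0 = opt0, opt1 = opt1, omega = omega,
              n_sample = as.integer(n_sample), seed = as.integer(seed))
  if (cfg$N < 2) stop("N must be >= 2")
  if (cfg$selfing < 0 || cfg$selfing > 1) stop("selfing must be in [0, 1]")
  if (cfg$mu_per_site < 0) stop("mu_per_site must be >= 0")
  if (cfg$rec_per_site < 0) stop("rec_per_site must be >= 0")
  if (regime != "neutral" && !(omega > 0))
    stop("omega must be > 0 for selective regimes")
  if (cfg$N_bottleneck > cfg$N)
    stop("N_bottleneck must not exceed N")
  if (cfg$N_bottleneck > 0 && cfg$t_shift <= 0)
    stop("a bottleneck requires t_shift > 0")
  final_n <- if (cfg$N_bottleneck > 0) cfg$N_bottleneck else cfg$N
  if (cfg$n_sample > final_n)
    stop("n_sample exceeds final population size")
  class(cfg) <- "sim_config"
  cfg
}

#' Run the forward Wright-Fisher simulation
#'
#' Discrete generations; each offspring is produced by selfing with
#' probability `selfing` (one parent, two independent meioses), otherwise by
#' outcrossing two parents, all sampled proportional to Gaussian fitness
#' (uniformly in the neutral regime). New mutations arise under infinite
#' sites at rate `mu_per_site * L` per gamete; crossovers are uniform at
#' rate `rec_per_site * L`. At `t_shift` the optimum moves `opt0 -> opt1`
#' (shifted_optimum regime) and the size drops to `N_bottleneck` if set.
#' The founder (ancestral) state carries no mutations, so the derived allele
#' at every site is the mutant allele; fixed mutations are retained in the
#' truth table with their fixation generation.
#'
#' @param config a [sim_config()].
#' @param include_fixed also include population-fixed mutations as
#'   (all-derived) columns of the sampled genotype matrix.
#' @return object of class `wf_sim`: list with `geno` (sampled accession
#'   dosage matrix), `variants` (variant table, `AA` ancestral = ref),
#'   `truth` (per-mutation id, pos, effect, origin_gen, fix_gen, final
#'   frequency, fixed flag), `population` (final haplotypes, mutation-id
#'   lists), `mean_trait` (per-generation mean trait), and `config`.
#' @export
simulate_population <- function(config, include_fixed = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  regime_code <- match(config$regime,
                       c("neutral", "stabilizing", "shifted_optimum")) - 1L
  raw <- .wf_simulate_cpp(config$N, config$N_bottleneck, config$t_shift,
                          config$generations, config$L, config$mu_per_site,
                          config$rec_per_site, config$selfing, config$p_null,
                          config$sigma_effect, config$p_large,
                          config$sigma_large, regime_code, config$opt0,
                          config$opt1, config$omega, config$n_founders)
  truth <- raw$mutations
  truth$id <- sprintf("m%06d", truth$id)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  truth$impact <- impact_class(truth$effect)

  sim <- structure(list(population = raw$haplotypes, truth = truth,
                        mean_trait = raw$mean_trait,
                        pop_size = raw$pop_size, config = config),
                   class = "wf_sim")
  sampled <- sample_accessions(sim, config$n_sample,
                               include_fixed = include_fixed)
  sim$geno <- sampled$geno
  sim$variants <- sampled$variants
  sim
}

# impact labels emulate annotation classes: zero-effect mutations are
# MODIFIER, non-null effects are binned LOW/MODERATE/HIGH by |effect| tertile
impact_class <- function(effect) {
  out <- rep("MODIFIER", length(effect))
  nz <- which(effect != 0)
  if (length(nz)) {
    q <- quantile(abs(effect[nz]), c(1 / 3, 2 / 3), names = FALSE, type = 7)
    out[nz] <- ifelse(abs(effect[nz]) <= q[1], "LOW",
                      ifelse(abs(effect[nz]) <= q[2], "MODERATE", "HIGH"))
  }
  out
}

#' Sample inbred accessions from a simulated population
#'
#' Draws `n` individuals without replacement and collapses each to a single
#' random gamete, representing a fully homozygous (inbred) line; dosages are
#' therefore in `{0, 1}` with no heterozygotes.
#'
#' @param sim a `wf_sim` object (see [simulate_population()]).
#' @param n number of accessions.
#' @param seed optional seed (`NULL` continues the current RNG stream).
#' @param include_fixed include population-fixed mutations as all-1 columns.
#' @return list with `geno` and `variants` for the sample.
#' @export
sample_accessions <- function(sim, n, seed = NULL, include_fixed = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n_ind <- length(sim$population) / 2
  if (n > n_ind) stop("n exceeds population size (", n_ind, ")")
  ind <- sample.int(n_ind, n)
  gam <- ifelse(runif(n) < 0.5, 2L * ind - 1L, 2L * ind)
  haps <- sim$population[gam]

  truth <- sim$truth
  seg <- truth[!truth$fixed, , drop = FALSE]
  present <- sort(unique(unlist(haps)))
  id_int <- as.integer(sub("^m", "", seg$id))
  seg <- seg[id_int %in% present, , drop = FALSE]
  keep <- seg
  if (include_fixed) {
    keep <- rbind(seg, truth[truth$fixed, , drop = FALSE])
    keep <- keep[order(keep$pos), , drop = FALSE]
  }
  geno <- matrix(0, nrow = n, ncol = nrow(keep),
                 dimnames = list(sprintf("line_%03d", seq_len(n)), keep$id))
  keep_int <- as.integer(sub("^m", "", keep$id))
  col_of <- setNames(seq_len(nrow(keep)), keep_int)
  for (i in seq_len(n)) {
    ids <- haps[[i]]
    ids <- ids[as.character(ids) %in% names(col_of)]
    geno[i, col_of[as.character(ids)]] <- 1
  }
  if (include_fixed && any(keep$fixed))
    geno[, keep$fixed] <- 1
  variants <- synth_variant_records(keep)
  list(geno = genotype_matrix(geno, line_ids = rownames(geno),
                              variant_ids = keep$id),
       variants = variants)
}

# deterministic synthetic ref/alt bases; ancestral (founder) allele is REF
synth_variant_records <- function(truth_rows) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[truth_rows$pos %% 4L + 1L]
  alt <- bases[(truth_rows$pos %/% 4L) %% 3L + 1L]
  alt <- ifelse(alt == ref, bases[(match(ref, bases)) %% 4L + 1L], alt)
  variant_table(chrom = "1", pos = truth_rows$pos, ref = ref, alt = alt,
                ancestral = "ref", impact = truth_rows$impact,
                id = truth_rows$id)
}

#' Simulate replicate-level phenotypes for sampled accessions
#'
#' Line genetic values are \eqn{g = X a} (dosage times true effect); the
#' environmental standard deviation is set so that
#' \eqn{var(g) / (var(g) + \sigma_e^2)} equals `h2_target`. Each line is
#' grown in `n_reps` replicates laid out in `n_blocks` randomized blocks
#' with Normal(0, `sd_block`) block effects. Seed count declines linearly
#' with flowering time (slope `beta_seed_slope` seeds/day) plus noise,
#' truncated at zero, emulating the negative flowering-time/fitness
#' relationship of drought-limited growing seasons.
#'
#' @param geno sampled genotype matrix.
#' @param truth simulator truth table (or any data.frame with `id` and
#'   `effect` covering the genotype columns).
#' @param h2_target target broad-sense heritability in (0, 1]; ignored when
#'   `sigma_e` is given.
#' @param sigma_e absolute environmental standard deviation (days) per
#'   replicate; the natural choice for a common-garden design where noise is
#'   shared across populations (heritability then differs between
#'   populations through their genetic variances).
#' @param n_blocks,n_reps block/replicate structure.
#' @param beta_seed_slope seeds lost per day of later flowering.
#' @param sd_block standard deviation of block effects (days).
#' @param seed_intercept,seed_sd intercept and noise sd of the seed model.
#' @param baseline trait value added to all lines (days), e.g. the fixed
#'   background `opt0`.
#' @param seed integer seed.
#' @return replicate-level phenotype table.
#' @export
simulate_phenotypes <- function(geno, truth, h2_target = 0.85,
                                sigma_e = NULL,
                                n_blocks = 4, n_reps = 4,
                                beta_seed_slope = 30, sd_block = 1,
                                seed_intercept = 3000, seed_sd = 300,
                                baseline = 0, seed = 1) {
  if (!(h2_target > 0 && h2_target <= 1))
    stop("h2_target must be in (0, 1]")
  eff <- setNames(truth$effect, truth$id)
  miss <- setdiff(colnames(geno), names(eff))
  if (length(miss)) stop("no true effect available for: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  set.seed(seed)
  g <- as.vector(geno %*% eff[colnames(geno)]) + baseline
  vg <- var(g)
  if (is.null(sigma_e)) {
    if (vg == 0) {
      if (h2_target == 1)
        stop("h2_target = 1 with zero genetic variance")
      warning("zero genetic variance; using sigma_e = 1")
      sigma_e <- 1
    } else {
      sigma_e <- sqrt(vg * (1 - h2_target) / h2_target)
    }
  }
  n <- nrow(geno)
  blocks <- rep_len(seq_len(n_blocks), n_reps)
  b_eff <- rnorm(n_blocks, 0, sd_block)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    fl <- g + b_eff[blocks[r]] + rnorm(n, 0, sigma_e)
    fl <- pmax(fl, 0)
    sc <- pmax(seed_intercept - beta_seed_slope * fl + rnorm(n, 0, seed_sd), 0)
    rows[[r]] <- data.frame(line = rownames(geno), rep = r,
                            block = paste0("B", blocks[r]),
                            flowering_days = fl, seed_count = sc,
                            stringsAsFactors = FALSE)
  }
  p <- do.call(rbind, rows)
  rownames(p) <- NULL
  validate_phenotypes(p)
  p
}

#' Simulate a mutation-limited origin-fixation adaptive walk
#'
#' One-dimensional Fisher geometric model: the population sits at trait
#' value `z` with optimum 0 and Gaussian fitness of width `omega`.
#' Candidate mutations of effect `r` are drawn one at a time from
#' `candidate_effect_dist`; the selection coefficient is
#' \eqn{s = w(z + r)/w(z) - 1} and a beneficial candidate fixes with
#' probability `min(1, 2s)` (Haldane's weak-selection approximation).
#' Accepted steps strictly reduce the distance to the optimum. The walk
#' stops when `|z| < eps` or after `max_steps` candidates.
#'
#' @param z0 starting trait displacement from the optimum.
#' @param omega Gaussian fitness width.
#' @param candidate_effect_dist function(n) drawing candidate effects
#'   (default standard normal).
#' @param max_steps maximum number of candidate mutations examined.
#' @param eps convergence distance.
#' @param seed integer seed.
#' @return data.frame of accepted substitutions: `step` (acceptance index),
#'   `effect`, `s`, `dist_before`, `dist_after`.
#' @export
simulate_origin_fixation_walk <- function(z0, omega = 5,
                                          candidate_effect_dist = function(n)
                                            rnorm(n, 0, 1),
                                          max_steps = 10000, eps = 0.05,
                                          seed = 1) {
  set.seed(seed)
  z <- z0
  acc <- list()
  k <- 0L
  for (i in seq_len(max_steps)) {
    if (abs(z) < eps) break
    r <- candidate_effect_dist(1)
    s <- exp((z^2 - (z + r)^2) / (2 * omega^2)) - 1
    if (s > 0 && runif(1) < min(1, 2 * s)) {
      k <- k + 1L
      acc[[k]] <- data.frame(step = k, effect = r, s = s,
                             dist_before = abs(z), dist_after = abs(z + r))
      z <- z + r
    }
  }
  if (!length(acc))
    return(data.frame(step = integer(), effect = numeric(), s = numeric(),
                      dist_before = numeric(), dist_after = numeric()))
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}
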