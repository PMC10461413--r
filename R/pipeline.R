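#' Default study-condition simulator configurations
#'
#' Two desk-scale regimes emulating the study contrast. The continent
#' regime is a large, long-established population under weak stabilizing
#' selection at its optimum: many small-effect variants segregate, the rare
#' large-effect class is purged, and a deeper coalescent history is
#' emulated by a higher neutral-marker mutation rate (the causal mutation
#' rate per site, mu * (1 - p_null) = 5e-8, is identical in both regimes).
#' The island regime is founded from two colonists (near-complete
#' bottleneck) while the trait optimum drops 15 days: strong directional
#' selection drives an adaptive walk in which a rare large-effect mutation
#' takes the first, dominant step and small-effect mutations fine-tune
#' afterwards. Lines self at rate 0.95 (outcrossing 5%).
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
island_config <- function(seed = 1) {
  sim_config(N = 200, N_bottleneck = 120, t_shift = 600, generations = 850,
             L = 1e5, mu_per_site = 2.5e-6, rec_per_site = 3e-5,
             selfing = 0.95, p_null = 0.98, sigma_effect = 0.5,
             p_large = 0.15, sigma_large = 20,
             regime = "shifted_optimum", opt0 = 0, opt1 = -20, omega = 6,
             n_sample = 100, seed = seed)
}

#' @rdname island_config
#' @export
continent_config <- function(seed = 1) {
  sim_config(N = 300, N_bottleneck = 0, t_shift = 0, generations = 900,
             L = 1e5, mu_per_site = 5e-6, rec_per_site = 3e-5,
             selfing = 0.95, p_null = 0.99, sigma_effect = 0.5,
             p_large = 0.15, sigma_large = 20,
             regime = "stabilizing", opt0 = 0, opt1 = 0, omega = 12,
             n_sample = 200, seed = seed)
}

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, command, seed, config) {
  man <- list(command = command, seed = seed, config = config,
              config_hash = config_hash(config))
  jsonlite::write_json(man, file.path(out_dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  man
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) {
    dir.create(d, recursive = TRUE)
    message("created output directory ", d)
  }
  d
}

#' Simulate a study population and write its files
#'
#' Runs the forward simulator and phenotype generator and writes
#' `genotypes.vcf`, `phenotypes.tsv`, `truth.tsv` and a manifest carrying
#' the seed and a config hash.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [sim_config()].
#' @param h2_target,n_reps,n_blocks,beta_seed_slope phenotype-generator
#'   parameters (see [simulate_phenotypes()]).
#' @param baseline flowering time (days) corresponding to trait value 0.
#' @param include_fixed include population-fixed variants in the VCF.
#' @return invisibly, list with the `wf_sim` object, phenotype table and
#'   file paths.
#' @export
run_sim <- function(out_dir, config = island_config(), h2_target = 0.85,
                    n_reps = 4, n_blocks = 4, beta_seed_slope = 30,
                    baseline = 80, include_fixed = FALSE) {
  ensure_dir(out_dir)
  sim <- simulate_population(config, include_fixed = include_fixed)
  pheno <- simulate_phenotypes(sim$geno, sim$truth, h2_target = h2_target,
                               n_blocks = n_blocks, n_reps = n_reps,
                               beta_seed_slope = beta_seed_slope,
                               baseline = baseline,
                               seed = config$seed + 1L)
  paths <- list(vcf = file.path(out_dir, "genotypes.vcf"),
                phenotypes = file.path(out_dir, "phenotypes.tsv"),
                truth = file.path(out_dir, "truth.tsv"))
  write_vcf(sim$geno, sim$variants, paths$vcf)
  man <- write_manifest(out_dir, "sim", config$seed, unclass(config))
  meta <- c(paste0("config_hash: ", man$config_hash),
            paste0("seed: ", config$seed))
  write_tsv(pheno, paths$phenotypes, meta = meta)
  write_tsv(sim$truth, paths$truth, meta = meta)
  invisible(list(sim = sim, pheno = pheno, paths = paths))
}

#' In-memory GWAS chain: aggregation, kinship, null fit, scan
#'
#' @param geno,variants genotype matrix and variant table.
#' @param pheno replicate-level phenotype table.
#' @param covariate_ids optional variant ids used as covariates.
#' @param maf_min minor-allele-frequency filter.
#' @param per_marker_lambda see [assoc_scan()].
#' @return list with `assoc`, `kinship`, `null_fit`, `h2`, `line_trait`.
#' @export
gwas_analysis <- function(geno, variants, pheno, covariate_ids = NULL,
                          maf_min = 0.05, per_marker_lambda = TRUE) {
  lt <- median_phenotype(pheno)
  common <- intersect(lt$line, rownames(geno))
  if (!length(common))
    stop("no lines shared between phenotypes (",
         paste(utils::head(lt$line, 3), collapse = ","),
         ", ...) and genotypes (",
         paste(utils::head(rownames(geno), 3), collapse = ","), ", ...)")
  K <- centered_kinship(geno[common, , drop = FALSE])
  y <- setNames(lt$flowering_days, lt$line)[common]
  null_fit <- fit_null_lmm(y, K)
  assoc <- assoc_scan(y, geno, K, variants = variants,
                      covariate_variants = covariate_ids,
                      maf_min = maf_min,
                      per_marker_lambda = per_marker_lambda)
  h2 <- broad_sense_h2(pheno)
  list(assoc = assoc, kinship = K, null_fit = null_fit, h2 = h2,
       line_trait = lt)
}

#' Run GWAS from files and write association outputs
#'
#' Reads a VCF and a replicate-level phenotype TSV, aggregates phenotypes
#' to per-line medians, builds the centered kinship, fits the null mixed
#' model and scans all variants; writes `assoc.tsv`, `kinship.tsv` and
#' `lmm_fit.json`.
#'
#' @param vcf,phenotypes input paths.
#' @param out_dir output directory.
#' @param covariate_ids,maf_min,het_policy options (see [assoc_scan()],
#'   [read_vcf()]).
#' @param seed recorded in metadata (the GWAS chain is deterministic).
#' @return invisibly, the [gwas_analysis()] result plus file paths.
#' @export
run_gwas <- function(vcf, phenotypes, out_dir, covariate_ids = NULL,
                     maf_min = 0.05, het_policy = "missing", seed = 1) {
  ensure_dir(out_dir)
  vv <- read_vcf(vcf, het_policy = het_policy)
  pheno <- read_phenotypes(phenotypes)
  res <- gwas_analysis(vv$geno, vv$variants, pheno,
                       covariate_ids = covariate_ids, maf_min = maf_min)
  cfg <- list(vcf = vcf, phenotypes = phenotypes,
              covariate_ids = covariate_ids, maf_min = maf_min,
              het_policy = het_policy)
  man <- write_manifest(out_dir, "gwas", seed, cfg)
  meta <- c(paste0("config_hash: ", man$config_hash), paste0("seed: ", seed),
            paste0("maf_min: ", maf_min))
  paths <- list(assoc = file.path(out_dir, "assoc.tsv"),
                kinship = file.path(out_dir, "kinship.tsv"),
                fit = file.path(out_dir, "lmm_fit.json"))
  write_tsv(res$assoc, paths$assoc, meta = meta)
  kin <- data.frame(line = rownames(res$kinship), res$kinship,
                    check.names = FALSE)
  write_tsv(kin, paths$kinship, meta = meta)
  nf <- res$null_fit
  jsonlite::write_json(list(lambda_hat = nf$lambda_hat,
                            sigma_g2 = nf$sigma_g2, sigma_e2 = nf$sigma_e2,
                            loglik = nf$loglik, pve = nf$pve, n = nf$n,
                            h2 = res$h2, config_hash = man$config_hash),
                       paths$fit, auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(paths = paths)))
}

#' In-memory architecture chain: local score, zones, clumps, representatives
#'
#' @param assoc association table (id, chrom, pos, beta, p_lrt).
#' @param geno,variants genotype matrix and variant table.
#' @param xi local-score tuning constant.
#' @param alpha per-chromosome significance level for the resampling
#'   threshold.
#' @param n_resample resampled null tracks per chromosome.
#' @param p1,window_kb,clump_r2 clumping parameters.
#' @param rep_r2 maximum r2 between locus representatives.
#' @param manual manually appended loci (see [representative_loci()]).
#' @param seed seed for the threshold resampling.
#' @return list with `tracks`, `thresholds`, `zones`, `clumps`, `loci`,
#'   `daf`.
#' @export
architecture_analysis <- function(assoc, geno, variants, xi = 2,
                                  alpha = 0.05, n_resample = 1000,
                                  p1 = 0.01, window_kb = 1000,
                                  clump_r2 = 0.8, rep_r2 = 0.5,
                                  manual = NULL, seed = 1) {
  tracks <- lindley_scores(assoc, xi = xi)
  thresholds <- numeric(length(tracks))
  names(thresholds) <- names(tracks)
  zones <- list()
  for (k in seq_along(tracks)) {
    m <- nrow(tracks[[k]])
    thresholds[k] <- significance_threshold(m, xi = xi, alpha = alpha,
                                            n_resample = n_resample,
                                            seed = seed + k)
    zones[[k]] <- call_zones(tracks[[k]], thresholds[k],
                             chrom = names(tracks)[k])
  }
  zones <- do.call(rbind, zones)
  if (is.null(zones))
    zones <- call_zones(data.frame(id = character(), pos = integer(),
                                   p = numeric(), s = numeric(),
                                   L = numeric()), Inf)
  cl <- clump(assoc, geno, p1 = p1, window_kb = window_kb, r2 = clump_r2)
  pol <- polarize(geno, variants)
  loci <- representative_loci(zones, tracks, assoc, geno, r2max = rep_r2,
                              daf = pol$daf, variants = variants,
                              manual = manual)
  list(tracks = tracks, thresholds = thresholds, zones = zones,
       clumps = cl, loci = loci, daf = pol$daf)
}

#' Run the architecture stage from files and write locus outputs
#'
#' Reads an association TSV (from [run_gwas()]) and the matching VCF, then
#' aggregates p-values into local scores, calls significant zones against
#' resampled thresholds, clumps, picks LD-pruned locus representatives, and
#' fits the effect-size distribution; writes `zones.tsv`, `clumps.tsv`,
#' `loci.tsv` and `arch_report.json`.
#'
#' @param assoc_path,vcf input paths.
#' @param out_dir output directory.
#' @param population population label in the report.
#' @param h2,pve optional heritabilities carried into the report.
#' @param mu mutation rate per site per generation used for the
#'   diversity-based N_e.
#' @param L_surveyed sites surveyed (default: max position in the VCF).
#' @param ages optional named vector of externally estimated allele ages.
#' @param ... further parameters for [architecture_analysis()].
#' @param seed threshold-resampling seed.
#' @return invisibly the per-population report component list.
#' @export
run_architecture <- function(assoc_path, vcf, out_dir,
                             population = "pop", h2 = NULL, pve = NULL,
                             mu = 7.5e-9, L_surveyed = NULL, ages = NULL,
                             seed = 1, ...) {
  ensure_dir(out_dir)
  assoc <- read_tsv(assoc_path)
  vv <- read_vcf(vcf)
  arch <- architecture_analysis(assoc, vv$geno, vv$variants, seed = seed, ...)
  if (is.null(L_surveyed)) L_surveyed <- max(vv$variants$pos)
  S <- sum(!is.na(arch$daf) & arch$daf > 0 & arch$daf < 1)
  theta <- watterson_theta(S, nrow(vv$geno), L_surveyed)
  Ne <- ne_from_theta(theta, mu)
  if (is.null(ages)) {
    p <- arch$loci$daf
    ok <- !is.na(p) & p > 0 & p < 1
    ages <- setNames(rep(NA_real_, nrow(arch$loci)), arch$loci$id)
    ages[ok] <- expected_allele_age(p[ok], Ne)
  }
  pop <- list(loci = arch$loci, n_zones = nrow(arch$zones),
              n_clumps = arch$clumps$n_clumps, h2 = h2, pve = pve,
              ages = ages, theta_w = theta, N_e = Ne)
  report <- assemble_report(setNames(list(pop), population))
  cfg <- list(assoc = assoc_path, vcf = vcf, population = population,
              mu = mu, seed = seed, ...)
  man <- write_manifest(out_dir, "architecture", seed, cfg)
  meta <- c(paste0("config_hash: ", man$config_hash), paste0("seed: ", seed))
  write_tsv(arch$zones, file.path(out_dir, "zones.tsv"), meta = meta)
  cl <- arch$clumps$clumps
  cl_df <- data.frame(
    index = vapply(cl, `[[`, character(1), "index"),
    members = vapply(cl, function(x) paste(x$members, collapse = ","),
                     character(1)), stringsAsFactors = FALSE)
  write_tsv(cl_df, file.path(out_dir, "clumps.tsv"), meta = meta)
  write_tsv(arch$loci, file.path(out_dir, "loci.tsv"), meta = meta)
  write_report(report, file.path(out_dir, "arch_report.json"))
  invisible(c(pop, list(arch = arch, report = report)))
}

#' Compare architecture reports across populations
#'
#' @param populations named list of per-population component lists (as
#'   produced by [run_architecture()] or assembled by hand).
#' @param path optional JSON output path.
#' @return combined `arch_report`.
#' @export
compare_architectures <- function(populations, path = NULL) {
  report <- assemble_report(populations)
  if (!is.null(path)) write_report(report, path)
  report
}

#' End-to-end two-regime experiment
#'
#' Simulates an island-like (bottleneck + optimum shift) and a
#' continent-like (large, stabilizing) population, generates replicated
#' phenotypes, runs the GWAS chain and the architecture chain on each, and
#' assembles the comparison report. Population-fixed trait-affecting
#' mutations that fixed after the optimum shift cannot appear in GWAS and
#' are appended manually to the island locus set with their true effects,
#' mirroring how known fixed causal variants are added from prior
#' functional work.
#'
#' @param seed root seed; stage seeds are derived from it.
#' @param island_cfg,continent_cfg simulator configurations.
#' @param n_resample null tracks per chromosome for the local-score
#'   threshold.
#' @param h2_target phenotype heritability (used only if `sigma_e` is NULL).
#' @param sigma_e shared absolute environmental standard deviation (days);
#'   the common-garden design implies the same noise for all populations, so
#'   realized heritability differs between regimes through genetic variance.
#' @param append_fixed append post-shift fixed causal mutations to the
#'   island locus set.
#' @param maf_min GWAS minor-allele-frequency filter.
#' @param baseline flowering time (days) of the trait origin z = 0; line
#'   flowering is `baseline` plus the genetic value plus noise.
#' @param covariate_rescan after a first scan, re-run the GWAS with the
#'   strongest zone's peak variant as a covariate and take the union of
#'   candidate loci (the standard two-pass design when a major-effect
#'   variant segregates; applied identically to both regimes).
#' @return list with `report` plus the full `island` and `continent`
#'   stage results.
#' @export
run_two_regimes <- function(seed = 1,
                            island_cfg = island_config(seed),
                            continent_cfg = continent_config(seed + 1000L),
                            n_resample = 500, h2_target = 0.95,
                            sigma_e = NULL,
                            append_fixed = TRUE, maf_min = 0.05,
                            baseline = 80, covariate_rescan = TRUE) {
  run_one <- function(cfg, label, manual_fixed) {
    sim <- simulate_population(cfg)
    pheno <- simulate_phenotypes(sim$geno, sim$truth, h2_target = h2_target,
                                 sigma_e = sigma_e,
                                 baseline = baseline, seed = cfg$seed + 1L)
    gw <- gwas_analysis(sim$geno, sim$variants, pheno, maf_min = maf_min)
    manual <- NULL
    if (manual_fixed) {
      tf <- sim$truth
      tf <- tf[tf$fixed & tf$effect != 0 & tf$fix_gen > cfg$t_shift, ,
               drop = FALSE]
      if (nrow(tf))
        manual <- data.frame(id = tf$id, chrom = "1", pos = tf$pos,
                             beta = tf$effect, daf = 1,
                             impact = tf$impact, stringsAsFactors = FALSE)
    }
    arch <- architecture_analysis(gw$assoc, sim$geno, sim$variants,
                                  n_resample = n_resample, manual = manual,
                                  seed = cfg$seed + 2L)
    if (covariate_rescan && NROW(arch$zones) >= 1) {
      top <- arch$zones$peak_id[which.max(arch$zones$peak_score)]
      gw2 <- gwas_analysis(sim$geno, sim$variants, pheno,
                           covariate_ids = top, maf_min = maf_min)
      arch2 <- architecture_analysis(gw2$assoc, sim$geno, sim$variants,
                                     n_resample = n_resample,
                                     manual = manual,
                                     seed = cfg$seed + 2L)
      arch <- merge_arch(arch, arch2, gw$assoc, sim$geno)
    }
    S <- ncol(sim$geno)
    theta <- watterson_theta(S, nrow(sim$geno), cfg$L)
    Ne <- ne_from_theta(theta, cfg$mu_per_site)
    p <- arch$loci$daf
    ok <- !is.na(p) & p > 0 & p < 1
    ages <- setNames(rep(NA_real_, nrow(arch$loci)), arch$loci$id)
    ages[ok] <- expected_allele_age(p[ok], Ne)
    list(loci = arch$loci, n_zones = nrow(arch$zones),
         n_clumps = arch$clumps$n_clumps, h2 = gw$h2,
         pve = gw$null_fit$pve, ages = ages, theta_w = theta, N_e = Ne,
         sim = sim, gwas = gw, arch = arch)
  }
  island <- run_one(island_cfg, "island", append_fixed)
  continent <- run_one(continent_cfg, "continent", FALSE)
  strip <- function(x) x[c("loci", "n_zones", "n_clumps", "h2", "pve",
                           "ages", "theta_w", "N_e")]
  report <- assemble_report(list(island = strip(island),
                                 continent = strip(continent)))
  list(report = report, island = island, continent = continent)
}


# Combine two architecture passes (initial scan, and the rescan with the
# strongest zone's peak variant as covariate).  Zone and clump counts come
# from the covariate-adjusted pass -- the major locus's haplotype otherwise
# shadows the rest of the genome -- plus one for the covariated locus
# itself.  Locus representatives are the union of both passes, re-thinned
# at r2 > 0.5 keeping the smaller-p member of any correlated pair.
merge_arch <- function(a1, a2, assoc1, geno, r2max = 0.5) {
  top <- a1$zones[which.max(a1$zones$peak_score), , drop = FALSE]
  zones <- top
  if (NROW(a2$zones)) {
    for (k in seq_len(nrow(a2$zones))) {
      z <- a2$zones[k, ]
      ov <- NROW(zones) && any(zones$chrom == z$chrom &
                                 zones$start_bp <= z$end_bp &
                                 zones$end_bp >= z$start_bp)
      if (!ov) zones <- rbind(zones, z)
    }
  }
  loci <- a1$loci
  add <- a2$loci[!a2$loci$id %in% loci$id, , drop = FALSE]
  loci <- rbind(loci, add)
  seg <- which(!loci$fixed)
  repeat {
    if (length(seg) < 2) break
    drop_id <- NULL
    for (i in seg) {
      for (j in seg) {
        if (j <= i) next
        rr <- pairwise_r2(geno, loci$id[i], loci$id[j])
        if (!is.na(rr) && rr > r2max) {
          pi <- loci$p_lrt[i]; pj <- loci$p_lrt[j]
          drop_id <- if (!is.na(pi) && !is.na(pj) && pi >= pj) loci$id[i]
                     else loci$id[j]
          break
        }
      }
      if (!is.null(drop_id)) break
    }
    if (is.null(drop_id)) break
    loci <- loci[loci$id != drop_id, , drop = FALSE]
    seg <- which(!loci$fixed)
  }
  a1$zones <- zones
  a1$loci <- loci
  # covariate-adjusted clumps, plus the covariated locus itself
  a1$clumps <- a2$clumps
  a1$clumps$n_clumps <- a2$clumps$n_clumps + 1L
  a1
}
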