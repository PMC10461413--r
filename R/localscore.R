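#' Lindley local scores from ordered association p-values
#'
#' Per chromosome, p-values (in physical order) are transformed to scores
#' \eqn{s_i = -\log_{10} p_i - \xi} and accumulated by the Lindley
#' recurrence \eqn{L_0 = 0,\ L_i = \max(0, L_{i-1} + s_i)}, so strongly
#' associated regions carry the most positive local scores. The tuning
#' constant \eqn{\xi} must exceed \eqn{\log_{10} e \approx 0.4343} so the
#' score drifts downward under the uniform null. Zero p-values are clamped
#' to the smallest representable positive double with a warning.
#'
#' @param assoc data.frame with columns `id`, `chrom`, `pos`, `p_lrt`
#'   (rows with `NA` p are dropped); must be sorted by (chrom, pos).
#' @param xi tuning constant (default 2).
#' @return named list (one element per chromosome) of data.frames with
#'   `id`, `pos`, `p`, `s`, `L`; attribute `xi`.
#' @export
lindley_scores <- function(assoc, xi = 2) {
  if (xi <= 0) stop("xi must be > 0")
  a <- assoc[!is.na(assoc$p_lrt), , drop = FALSE]
  if (any(a$p_lrt < 0 | a$p_lrt > 1)) stop("p-values must lie in (0, 1]")
  if (any(a$p_lrt == 0)) {
    warning("p = 0 clamped to .Machine$double.xmin")
    a$p_lrt[a$p_lrt == 0] <- .Machine$double.xmin
  }
  o <- order(a$chrom, a$pos)
  if (!identical(o, seq_len(nrow(a)))) a <- a[o, , drop = FALSE]
  out <- lapply(split(a, a$chrom), function(ch) {
    s <- -log10(ch$p_lrt) - xi
    data.frame(id = ch$id, pos = ch$pos, p = ch$p_lrt, s = s,
               L = lindley(s), stringsAsFactors = FALSE)
  })
  attr(out, "xi") <- xi
  out
}

# Lindley recurrence for one score vector
lindley <- function(s) {
  L <- numeric(length(s))
  acc <- 0
  for (i in seq_along(s)) {
    acc <- max(0, acc + s[i])
    L[i] <- acc
  }
  L
}

#' Resampling significance threshold for Lindley local scores
#'
#' Draws `n_resample` i.i.d. uniform p-value tracks of length `m`, computes
#' the maximum Lindley score of each, and returns the empirical
#' \eqn{(1-\alpha)} quantile. Requires negative score drift under the null,
#' i.e. \eqn{\xi > \log_{10} e}.
#'
#' @param m number of variants on the chromosome.
#' @param xi tuning constant used for the scores.
#' @param alpha per-chromosome significance level (default 0.05).
#' @param n_resample number of null tracks (default 1000).
#' @param seed integer seed.
#' @return numeric threshold (>= 0).
#' @export
significance_threshold <- function(m, xi = 2, alpha = 0.05,
                                   n_resample = 1000, seed = 1) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (xi <= log10(exp(1)))
    stop("xi must exceed log10(e) ~ 0.4343 for negative drift under the ",
         "null; increase xi")
  set.seed(seed)
  # vectorized over resamples: Lindley recurrence down the track
  L <- numeric(n_resample)
  mx <- numeric(n_resample)
  for (i in seq_len(m)) {
    s <- -log10(runif(n_resample)) - xi
    L <- pmax(0, L + s)
    mx <- pmax(mx, L)
  }
  as.numeric(quantile(mx, 1 - alpha, type = 7, names = FALSE))
}

#' Call significant zones from a Lindley track
#'
#' A zone is a maximal run of consecutive positive local scores whose
#' maximum exceeds the threshold; runs are delimited by the resets of the
#' Lindley process at zero. Each zone is one candidate locus. The peak is
#' the leftmost position of the maximal score within the run.
#'
#' @param track one chromosome's data.frame from [lindley_scores()].
#' @param threshold numeric threshold (e.g. [significance_threshold()]).
#' @param chrom chromosome label recorded in the output.
#' @return data.frame of zones: `chrom`, `start_idx`, `end_idx`,
#'   `start_bp`, `end_bp`, `peak_score`, `peak_id`, `peak_idx`.
#' @export
call_zones <- function(track, threshold, chrom = NA_character_) {
  L <- track$L
  pos <- L > 0
  empty <- data.frame(chrom = character(), start_idx = integer(),
                      end_idx = integer(), start_bp = integer(),
                      end_bp = integer(), peak_score = numeric(),
                      peak_id = character(), peak_idx = integer(),
                      stringsAsFactors = FALSE)
  if (!any(pos)) return(empty)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zones <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- L[i0:i1]
    if (max(seg) > threshold) {
      pk <- i0 + which.max(seg) - 1L  # leftmost maximum
      zones[[length(zones) + 1L]] <- data.frame(
        chrom = chrom, start_idx = i0, end_idx = i1,
        start_bp = track$pos[i0], end_bp = track$pos[i1],
        peak_score = L[pk], peak_id = track$id[pk], peak_idx = pk,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(zones)) return(empty)
  do.call(rbind, zones)
}

#' Squared correlation (r2) between two variant columns
#'
#' Squared Pearson correlation of dosages over pairwise-complete lines.
#' Returns `NA` when fewer than two complete pairs remain or either column
#' has zero variance among them.
#'
#' @param geno genotype matrix.
#' @param i,j column indices or variant ids.
#' @return r-squared in \[0, 1\] or `NA`.
#' @export
pairwise_r2 <- function(geno, i, j) {
  x <- geno[, i]
  y <- geno[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Greedy LD clumping of association results
#'
#' Mirrors the standard clumping rule: repeatedly take the unassigned
#' variant with the smallest p-value below `p1` as an index; all unassigned
#' variants on the same chromosome within `window_kb` and with
#' \eqn{r^2 >} `r2` with the index join its clump. The number of clumps is
#' a polygenicity estimate.
#'
#' @param assoc association table (`id`, `chrom`, `pos`, `p_lrt`).
#' @param geno genotype matrix with matching variant columns.
#' @param p1 index-variant significance threshold (default 0.01).
#' @param window_kb maximum distance from index in kb (default 1000, 1 Mbp).
#' @param r2 LD threshold for clump membership (default 0.8).
#' @return list with `clumps` (list of `index` id and `members` ids) and
#'   `n_clumps`.
#' @export
clump <- function(assoc, geno, p1 = 0.01, window_kb = 1000, r2 = 0.8) {
  a <- assoc[!is.na(assoc$p_lrt), , drop = FALSE]
  a <- a[a$p_lrt < p1, , drop = FALSE]
  a <- a[order(a$p_lrt, a$chrom, a$pos), , drop = FALSE]
  unassigned <- setNames(rep(TRUE, nrow(a)), a$id)
  clumps <- list()
  for (k in seq_len(nrow(a))) {
    id <- a$id[k]
    if (!unassigned[id]) next
    unassigned[id] <- FALSE
    cand <- a[unassigned[a$id], , drop = FALSE]
    cand <- cand[cand$chrom == a$chrom[k] &
                   abs(cand$pos - a$pos[k]) <= window_kb * 1000, ,
                 drop = FALSE]
    members <- character()
    for (cid in cand$id) {
      rr <- pairwise_r2(geno, id, cid)
      if (!is.na(rr) && rr > r2) {
        members <- c(members, cid)
        unassigned[cid] <- FALSE
      }
    }
    clumps[[length(clumps) + 1L]] <- list(index = id, members = members)
  }
  list(clumps = clumps, n_clumps = length(clumps))
}

#' Sliding-window LD pruning
#'
#' Standard `indep-pairwise`-style pruning: within each window of `window`
#' consecutive retained variants, while any pair has \eqn{r^2 >} `r2`, the
#' later-positioned member of the pair is removed; the window then slides
#' by `step` variants. Removals accumulate globally.
#'
#' @param geno genotype matrix with variants in position order.
#' @param window window size in variants (default 50).
#' @param step window step in variants (default 10).
#' @param r2 LD threshold (default 0.3).
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(geno, window = 50, step = 10, r2 = 0.3) {
  m <- ncol(geno)
  keep <- rep(TRUE, m)
  if (m < 2) return(colnames(geno))
  starts <- seq(1L, max(1L, m), by = step)
  for (st in starts) {
    en <- min(m, st + window - 1L)
    idx <- st:en
    repeat {
      act <- idx[keep[idx]]
      if (length(act) < 2) break
      removed <- FALSE
      done <- FALSE
      for (ii in seq_len(length(act) - 1)) {
        for (jj in (ii + 1):length(act)) {
          rr <- pairwise_r2(geno, act[ii], act[jj])
          if (!is.na(rr) && rr > r2) {
            keep[act[jj]] <- FALSE  # drop the later-positioned member
            removed <- TRUE
            done <- TRUE
            break
          }
        }
        if (done) break
      }
      if (!removed) break
    }
    if (en == m) break
  }
  colnames(geno)[keep]
}

#' One representative variant per candidate locus, LD-pruned
#'
#' For each significant zone the variant with the smallest p-value is taken
#' as the locus representative (ties broken leftmost). Representatives in
#' mutual LD are then thinned: while any pair has \eqn{r^2 >} `r2max`, the
#' one with the larger p-value is dropped. Known causal loci fixed in the
#' population (which cannot appear in GWAS) can be appended manually.
#'
#' @param zones zone table (see [call_zones()]), needing `start_idx`,
#'   `end_idx` per chromosome track, or a combined table with `chrom`.
#' @param tracks the [lindley_scores()] list the zones were called from.
#' @param assoc association table with `id`, `beta`, `p_lrt`.
#' @param geno genotype matrix (for r2).
#' @param r2max maximum r2 between retained representatives (default 0.5).
#' @param daf optional named derived-allele-frequency vector (from
#'   [polarize()]) copied onto the output.
#' @param variants optional variant table supplying impact labels.
#' @param manual optional data.frame of manually appended loci with columns
#'   `id`, `chrom`, `pos`, `beta`, `daf`, `impact` (flagged `fixed = TRUE`).
#' @return data.frame: `id`, `chrom`, `pos`, `beta`, `p_lrt`, `daf`,
#'   `impact`, `fixed`.
#' @export
representative_loci <- function(zones, tracks, assoc, geno, r2max = 0.5,
                                daf = NULL, variants = NULL, manual = NULL) {
  reps <- list()
  for (k in seq_len(NROW(zones))) {
    z <- zones[k, ]
    tr <- tracks[[z$chrom]]
    ids <- tr$id[z$start_idx:z$end_idx]
    p <- assoc$p_lrt[match(ids, assoc$id)]
    if (all(is.na(p))) {
      warning("zone ", k, " has no testable variant; dropped")
      next
    }
    best <- ids[which.min(p)]  # which.min returns leftmost on ties
    reps[[length(reps) + 1L]] <- best
  }
  ids <- unique(unlist(reps))
  out <- assoc[match(ids, assoc$id), c("id", "chrom", "pos", "beta", "p_lrt"),
               drop = FALSE]
  # prune representatives in mutual LD: drop the weaker (larger p) member
  repeat {
    if (nrow(out) < 2) break
    drop_id <- NULL
    for (i in seq_len(nrow(out) - 1)) {
      for (j in (i + 1):nrow(out)) {
        rr <- pairwise_r2(geno, out$id[i], out$id[j])
        if (!is.na(rr) && rr > r2max) {
          drop_id <- if (out$p_lrt[i] >= out$p_lrt[j]) out$id[i] else out$id[j]
          break
        }
      }
      if (!is.null(drop_id)) break
    }
    if (is.null(drop_id)) break
    out <- out[out$id != drop_id, , drop = FALSE]
  }
  out$daf <- if (!is.null(daf)) unname(daf[out$id])
             else rep(NA_real_, nrow(out))
  out$impact <- if (!is.null(variants))
    variants$impact[match(out$id, variants$id)]
  else rep(NA_character_, nrow(out))
  out$fixed <- rep(FALSE, nrow(out))
  if (!is.null(manual) && nrow(manual)) {
    man <- data.frame(id = manual$id, chrom = manual$chrom, pos = manual$pos,
                      beta = manual$beta, p_lrt = NA_real_, daf = manual$daf,
                      impact = manual$impact, fixed = TRUE,
                      stringsAsFactors = FALSE)
    out <- rbind(out, man)
  }
  rownames(out) <- NULL
  out
}
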