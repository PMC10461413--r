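#' Construct and validate a variant table
#'
#' A variant table describes one biallelic variant per row. It is a plain
#' `data.frame` with columns `chrom`, `pos` (1-based bp), `ref`, `alt`,
#' `ancestral` (one of `"ref"`, `"alt"`, `"unknown"`), `impact` (one of
#' `"HIGH"`, `"MODERATE"`, `"LOW"`, `"MODIFIER"`, `NA`) and a unique `id`.
#' Rows must be sorted by (chrom, pos).
#'
#' @param chrom,pos,ref,alt,ancestral,impact,id column vectors; `ancestral`
#'   defaults to `"unknown"`, `impact` to `NA`, `id` to `chrom:pos:ref:alt`.
#' @return a validated `data.frame` of variants.
#' @export
variant_table <- function(chrom, pos, ref, alt,
                          ancestral = "unknown", impact = NA_character_,
                          id = NULL) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (is.null(id)) id <- paste(chrom, pos, ref, alt, sep = ":")
  v <- data.frame(chrom = chrom, pos = as.integer(pos),
                  ref = ref, alt = alt,
                  ancestral = rep_len(as.character(ancestral), n),
                  impact = rep_len(as.character(impact), n),
                  id = as.character(id), stringsAsFactors = FALSE)
  validate_variant_table(v)
  v
}

validate_variant_table <- function(v) {
  stopifnot(is.data.frame(v))
  need <- c("chrom", "pos", "ref", "alt", "ancestral", "impact", "id")
  missing_cols <- setdiff(need, names(v))
  if (length(missing_cols))
    stop("variant table missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(v) == 0) return(invisible(v))
  if (any(v$pos < 1)) stop("variant positions must be >= 1")
  if (any(v$ref == v$alt)) stop("ref and alt alleles must differ")
  if (anyDuplicated(v$id)) stop("duplicate variant ids")
  bad_anc <- !v$ancestral %in% c("ref", "alt", "unknown")
  if (any(bad_anc)) stop("ancestral must be one of ref/alt/unknown")
  o <- order(v$chrom, v$pos)
  if (!identical(o, seq_len(nrow(v))))
    stop("variants must be sorted by (chrom, pos)")
  invisible(v)
}

#' Construct a genotype dosage matrix for inbred lines
#'
#' Dosages are haploid `{0, 1, NA}` codes, one row per (fully inbred) line
#' and one column per variant; 1 is the alt (or, after [polarize()], the
#' derived) allele.
#'
#' @param values numeric matrix over `{0, 1, NA}`.
#' @param line_ids,variant_ids row/column labels.
#' @return the matrix with dimnames set, after validation.
#' @export
genotype_matrix <- function(values, line_ids = rownames(values),
                            variant_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(line_ids) || is.null(variant_ids))
    stop("line_ids and variant_ids are required")
  if (length(line_ids) != nrow(values) || length(variant_ids) != ncol(values))
    stop("dimension mismatch between values and id lists")
  ok <- values %in% c(0, 0.5, 1) | is.na(values)
  if (!all(ok)) stop("genotype entries must be 0, 1 or NA (0.5 only under het_policy = \"half\")")
  dimnames(values) <- list(as.character(line_ids), as.character(variant_ids))
  storage.mode(values) <- "double"
  values
}

#' Per-variant missingness fraction of a genotype matrix
#' @param geno genotype matrix from [genotype_matrix()].
#' @return named numeric vector in \[0, 1\].
#' @export
missingness <- function(geno) colMeans(is.na(geno))

#' Validate a replicate-level phenotype table
#'
#' Columns: `line`, `rep`, `block`, `flowering_days`, `seed_count`
#' (seed counts may be missing). `(line, rep)` pairs must be unique and
#' flowering times non-negative.
#'
#' @param p data.frame.
#' @return the table, invisibly, or an error.
#' @export
validate_phenotypes <- function(p) {
  need <- c("line", "rep", "block", "flowering_days", "seed_count")
  missing_cols <- setdiff(need, names(p))
  if (length(missing_cols))
    stop("phenotype table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.na(p$flowering_days) & p$flowering_days < 0))
    stop("flowering_days must be non-negative")
  if (anyDuplicated(p[, c("line", "rep")]))
    stop("duplicate (line, rep) pairs in phenotype table")
  invisible(p)
}

#' Aggregate replicate phenotypes to per-line medians
#'
#' The per-line phenotype is the median flowering time across replicates
#' (midpoint convention for even counts, as in [stats::median()]); seed
#' counts are summed per line. Lines whose replicates are all missing are
#' dropped with a warning.
#'
#' @param pheno replicate-level phenotype table (see [validate_phenotypes()]).
#' @return data.frame with columns `line`, `flowering_days`, `seed_total`.
#' @export
median_phenotype <- function(pheno) {
  validate_phenotypes(pheno)
  lines <- unique(pheno$line)
  med <- vapply(lines, function(l) {
    v <- pheno$flowering_days[pheno$line == l]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    median(v)
  }, numeric(1))
  seed <- vapply(lines, function(l) {
    v <- pheno$seed_count[pheno$line == l]
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  }, numeric(1))
  drop <- is.na(med)
  if (any(drop))
    warning(sum(drop), " line(s) with no non-missing flowering time dropped")
  data.frame(line = as.character(lines[!drop]),
             flowering_days = med[!drop],
             seed_total = seed[!drop],
             stringsAsFactors = FALSE)
}

#' Polarize a genotype matrix to derived-allele coding
#'
#' Where the variant table records `ancestral = "alt"`, dosages are flipped
#' (0 becomes 1 and vice versa) so that 1 always counts the derived allele.
#' Variants with unknown ancestral state are flagged (`polarized = FALSE`)
#' and their derived allele frequency is `NA`; they are retained for
#' association but excluded from frequency-polarity analyses.
#'
#' @param geno genotype matrix (alt-dosage coding).
#' @param variants matching variant table.
#' @return list with `geno` (derived coding), `daf` (named derived allele
#'   frequency vector, `NA` where unknown ancestral or all dosages missing)
#'   and `polarized` (logical vector).
#' @export
polarize <- function(geno, variants) {
  validate_variant_table(variants)
  if (!identical(colnames(geno), variants$id))
    stop("genotype columns do not match variant ids")
  flip <- variants$ancestral == "alt"
  geno[, flip] <- 1 - geno[, flip, drop = FALSE]
  daf <- colMeans(geno, na.rm = TRUE)
  daf[is.nan(daf)] <- NA_real_  # all-missing columns
  unknown <- variants$ancestral == "unknown"
  daf[unknown] <- NA_real_
  list(geno = geno, daf = daf, polarized = !unknown)
}
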