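#' Read a biallelic VCF into a dosage matrix and variant table
#'
#' Minimal VCF 4.x text reader for inbred-line genotype data. Only the GT
#' field is used; dosages are haploid: homozygous reference 0, homozygous
#' alternate 1, missing `NA`. Heterozygous calls are handled per
#' `het_policy`: `"missing"` (default; residual heterozygosity in selfing
#' lines is treated as call error) or `"half"` (dosage 0.5). The `AA` INFO
#' key, when present and equal to the ref or alt allele, fills the
#' `ancestral` column; any other value gives `"unknown"`. An `IMPACT` INFO
#' key fills the `impact` column. Multiallelic rows are skipped with a
#' message.
#'
#' @param path VCF file (plain text or gzip).
#' @param het_policy `"missing"` or `"half"`.
#' @return list with `geno` (lines x variants dosage matrix), `variants`
#'   (variant table) and `n_multiallelic_skipped`.
#' @export
read_vcf <- function(path, het_policy = c("missing", "half")) {
  het_policy <- match.arg(het_policy)
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM\t", lines)
  if (length(hdr_i) != 1)
    stop("malformed VCF: expected exactly one #CHROM header line in ", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10)
    stop("VCF has no sample columns (line ", hdr_i, ")")
  samples <- hdr[-(1:9)]

  body_i <- seq_along(lines)[-seq_len(hdr_i)]
  body_i <- body_i[nzchar(lines[body_i])]
  n_skip <- 0L
  rows <- list()
  dosages <- list()
  for (i in body_i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("malformed VCF row at line ", i, ": expected ", length(hdr),
           " fields, got ", length(f))
    if (grepl(",", f[5], fixed = TRUE)) {  # multiallelic
      n_skip <- n_skip + 1L
      next
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("unparsable POS at line ", i)
    info <- parse_info(f[8])
    anc <- "unknown"
    if (!is.null(info[["AA"]])) {
      if (identical(info[["AA"]], f[4])) anc <- "ref"
      else if (identical(info[["AA"]], f[5])) anc <- "alt"
    }
    impact <- if (!is.null(info[["IMPACT"]])) info[["IMPACT"]] else NA_character_
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("no GT field at line ", i)
    gt <- vapply(f[-(1:9)], function(s)
      strsplit(s, ":", fixed = TRUE)[[1]][gt_idx], character(1),
      USE.NAMES = FALSE)
    dosages[[length(dosages) + 1L]] <- gt_to_dosage(gt, het_policy, i)
    id <- if (f[3] == "." || !nzchar(f[3]))
      paste(f[1], f[2], f[4], f[5], sep = ":") else f[3]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = f[1], pos = pos, ref = f[4], alt = f[5],
      ancestral = anc, impact = impact, id = id, stringsAsFactors = FALSE)
  }
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip, " multiallelic row(s)")
  if (!length(rows)) {
    variants <- variant_table(character(), integer(), character(), character())
    geno <- matrix(numeric(0), nrow = length(samples), ncol = 0,
                   dimnames = list(samples, character(0)))
    return(list(geno = geno, variants = variants,
                n_multiallelic_skipped = n_skip))
  }
  variants <- do.call(rbind, rows)
  if (anyDuplicated(variants$id))
    stop("duplicate variant id(s): ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  validate_variant_table(variants)
  geno <- do.call(cbind, dosages)
  geno <- genotype_matrix(geno, line_ids = samples, variant_ids = variants$id)
  list(geno = geno, variants = variants, n_multiallelic_skipped = n_skip)
}

parse_info <- function(s) {
  if (s == "." || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    out[[kv[1]]] <- if (length(kv) > 1) kv[2] else TRUE
  }
  out
}

gt_to_dosage <- function(gt, het_policy, line_no) {
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    a <- a[a != ""]
    if (!length(a) || all(a == "."))
      return(NA_real_)
    if (any(a == ".")) return(NA_real_)
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a) || any(a > 1))
      stop("unparsable GT at line ", line_no)
    if (length(a) == 1) return(as.numeric(a))
    if (a[1] == a[2]) return(as.numeric(a[1]))
    if (het_policy == "half") 0.5 else NA_real_
  }, numeric(1))
}

#' Write a dosage matrix and variant table as a plain-text VCF
#'
#' Inverse of [read_vcf()]: dosage 0 becomes `0/0`, 1 becomes `1/1`,
#' `NA` becomes `./.` and 0.5 becomes `0/1`. Ancestral state is written as
#' the `AA` INFO key (`AA=.` when unknown) and impact classes as `IMPACT`.
#' Round trip: `read_vcf(write_vcf(...))` reproduces dosages, positions,
#' ancestral tags and impact labels.
#'
#' @param geno,variants consistent genotype matrix and variant table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, variants, path) {
  validate_variant_table(variants)
  if (ncol(geno) != nrow(variants) ||
      (ncol(geno) > 0 && !identical(colnames(geno), variants$id)))
    stop("genotype columns do not match variant ids")
  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Predicted impact class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  body <- character(nrow(variants))
  for (j in seq_len(nrow(variants))) {
    v <- variants[j, ]
    aa <- switch(v$ancestral, ref = v$ref, alt = v$alt, unknown = ".")
    info <- paste0("AA=", aa)
    if (!is.na(v$impact)) info <- paste0(info, ";IMPACT=", v$impact)
    gt <- dosage_to_gt(geno[, j])
    body[j] <- paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".",
                       info, "GT", gt), collapse = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  ok <- tryCatch({
    writeLines(c(meta, body), con)
    TRUE
  }, error = function(e) stop("failed writing VCF to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0] <- "0/0"
  out[!is.na(d) & d == 1] <- "1/1"
  out[!is.na(d) & d == 0.5] <- "0/1"
  out
}

#' Read a replicate-level phenotype TSV
#'
#' Expected header: `line`, `rep`, `block`, `flowering_days`, `seed_count`
#' (tab-separated; `NA` allowed in `seed_count`).
#'
#' @param path TSV file.
#' @return validated phenotype table.
#' @export
read_phenotypes <- function(path) {
  p <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  p$line <- as.character(p$line)
  p$block <- as.character(p$block)
  p$flowering_days <- as.numeric(p$flowering_days)
  p$seed_count <- as.numeric(p$seed_count)
  validate_phenotypes(p)
  p
}

#' Write a data frame as TSV with commented metadata header
#' @param x data.frame. @param path file. @param meta character vector of
#'   metadata lines (written as `# key: value`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) as.character(signif(v, 10)))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file.
#' @return data.frame (metadata lines in attribute `"meta"`).
#' @export
read_tsv <- function(path) {
  lines <- readLines(path, n = 200)
  meta <- sub("^# ", "", lines[startsWith(lines, "# ")])
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  attr(x, "meta") <- meta
  x
}
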