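test_that("toy VCF parses: dosages, het policy, AA tag, multiallelic skip", {
  f <- toy_vcf(tempfile(fileext = ".vcf"))
  expect_message(v <- read_vcf(f), "multiallelic")
  expect_equal(v$n_multiallelic_skipped, 1L)
  expect_equal(rownames(v$geno), c("s1", "s2", "s3"))
  expect_equal(unname(v$geno[, "va"]), c(0, 1, NA))  # het -> missing
  expect_equal(unname(v$geno[, "vb"]), c(0, 1, NA))  # ./. -> missing
  expect_equal(v$variants$ancestral,
               c("ref", "alt", "unknown", "ref"))
  expect_equal(v$variants$impact, c(NA, NA, NA, "HIGH"))

  vh <- suppressMessages(read_vcf(f, het_policy = "half"))
  expect_equal(unname(vh$geno[, "va"]), c(0, 1, 0.5))
})

test_that("VCF errors carry line numbers; duplicate ids rejected", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("1", "100", "x", "A", "T", ".", ".", ".", "GT", "0/0", sep = "\t"),
    paste("1", "200", "x", "C", "G", ".", ".", ".", "GT", "1/1", sep = "\t")
  ), f)
  expect_error(read_vcf(f), "duplicate variant id")

  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("1", "100", "x", "A", "T", ".", ".", ".", "GT", sep = "\t")
  ), f)
  expect_error(read_vcf(f), "line 3")
})

test_that("VCF round trip preserves dosages, positions, AA tags and impacts", {
  g <- random_geno(5, 10, miss = 0.1, seed = 3)
  anc <- rep(c("ref", "alt", "unknown"), length.out = 10)
  imp <- rep(c("HIGH", "MODERATE", NA, "LOW", "MODIFIER"), 2)
  v <- variant_table(chrom = rep(c("1", "2"), each = 5),
                     pos = rep(c(10L, 20L, 35L, 47L, 90L), 2),
                     ref = "A", alt = "G", ancestral = anc, impact = imp,
                     id = colnames(g))
  f <- tempfile(fileext = ".vcf")
  write_vcf(g, v, f)
  back <- read_vcf(f)
  expect_equal(unname(back$geno), unname(g))
  expect_equal(back$variants$pos, v$pos)
  expect_equal(back$variants$ancestral, v$ancestral)
  expect_equal(back$variants$impact, v$impact)
  expect_equal(back$variants$id, v$id)
})

test_that("empty matrix writes a valid header-only VCF", {
  v <- variant_table(character(), integer(), character(), character())
  g <- matrix(numeric(0), nrow = 2, ncol = 0,
              dimnames = list(c("a", "b"), NULL))
  f <- tempfile(fileext = ".vcf")
  write_vcf(g, v, f)
  back <- read_vcf(f)
  expect_equal(ncol(back$geno), 0L)
  expect_equal(rownames(back$geno), c("a", "b"))
})

test_that("missing dosages round trip as ./. genotypes", {
  g <- genotype_matrix(matrix(c(0, NA, 1, NA), 2, 2),
                       line_ids = c("a", "b"), variant_ids = c("x", "y"))
  v <- variant_table("1", c(1L, 2L), "A", "T", id = c("x", "y"))
  f <- tempfile(fileext = ".vcf")
  write_vcf(g, v, f)
  txt <- readLines(f)
  expect_true(any(grepl("\\./\\.", txt)))
  expect_equal(unname(read_vcf(f)$geno), unname(g))
})

test_that("polarize flips alt-ancestral columns and flags unknowns", {
  g <- genotype_matrix(matrix(c(0, 1, 1,  0, 1, 1,  0, 1, NA), 3, 3),
                       line_ids = c("a", "b", "c"),
                       variant_ids = c("v1", "v2", "v3"))
  v <- variant_table("1", 1:3, "A", "T",
                     ancestral = c("ref", "alt", "unknown"),
                     id = c("v1", "v2", "v3"))
  p <- polarize(g, v)
  expect_equal(unname(p$geno[, "v1"]), c(0, 1, 1))
  expect_equal(unname(p$geno[, "v2"]), c(1, 0, 0))   # flipped
  expect_equal(unname(p$daf["v1"]), 2 / 3)
  expect_equal(unname(p$daf["v2"]), 1 / 3)
  expect_true(is.na(p$daf["v3"]))                    # unknown ancestral
  expect_equal(p$polarized, c(TRUE, TRUE, FALSE))

  # involution: flipping twice restores the input
  p2 <- polarize(p$geno, v)
  expect_equal(unname(p2$geno[, "v2"]), unname(g[, "v2"]))
})

test_that("all-missing column has undefined DAF", {
  g <- genotype_matrix(matrix(NA_real_, 3, 1),
                       line_ids = c("a", "b", "c"), variant_ids = "v1")
  v <- variant_table("1", 1L, "A", "T", ancestral = "ref", id = "v1")
  expect_true(is.na(polarize(g, v)$daf["v1"]))
})

test_that("DAF stays in [0,1] and flip symmetry holds on random fixtures", {
  for (s in 1:5) {
    g <- random_geno(8, 12, seed = s)
    v <- variant_table("1", seq_len(12) * 10L, "A", "T",
                       ancestral = "ref", id = colnames(g))
    daf <- polarize(g, v)$daf
    expect_true(all(daf >= 0 & daf <= 1))
    v2 <- v; v2$ancestral <- "alt"
    daf2 <- polarize(g, v2)$daf
    expect_equal(unname(daf + daf2), rep(1, 12))
  }
})

test_that("phenotype reading validates structure", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("line\trep\tblock\tflowering_days\tseed_count",
               "a\t1\tB1\t30\t100", "a\t2\tB2\t34\tNA"), f)
  p <- read_phenotypes(f)
  expect_equal(nrow(p), 2)
  expect_true(is.na(p$seed_count[2]))

  writeLines(c("line\trep\tblock\tflowering_days\tseed_count",
               "a\t1\tB1\t-3\t100"), f)
  expect_error(read_phenotypes(f), "non-negative")

  writeLines(c("line\trep\tblock\tflowering_days\tseed_count",
               "a\t1\tB1\t30\t100", "a\t1\tB2\t31\t90"), f)
  expect_error(read_phenotypes(f), "duplicate")
})

test_that("median aggregation uses midpoints and drops empty lines", {
  p <- data.frame(line = c("a", "a", "a", "b", "b", "c", "d"),
                  rep = c(1, 2, 3, 1, 2, 1, 1),
                  block = "B1",
                  flowering_days = c(30, 32, 100, 30, 34, 41, NA),
                  seed_count = c(10, 20, NA, 5, 5, 7, 2))
  expect_warning(m <- median_phenotype(p), "dropped")
  expect_equal(m$flowering_days[m$line == "a"], 32)   # robust to outlier
  expect_equal(m$flowering_days[m$line == "b"], 32)   # midpoint
  expect_equal(m$flowering_days[m$line == "c"], 41)
  expect_false("d" %in% m$line)
  expect_equal(m$seed_total[m$line == "a"], 30)
})
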