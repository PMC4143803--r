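# Genotype / phenotype / gene-map I-O.

test_that("read_vcf parses GT fields into ALT dosages", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"),
                      list("0/0\t0/1\t1/1",
                           "0/1\t./.\t1|1",
                           "0/0\t0/0\t0/1"))
  G <- read_vcf(f)
  expect_equal(dim(G), c(3L, 3L))
  expect_equal(unname(G$dosages[, 1]), c(0, 1, 2))
  expect_equal(unname(G$dosages[, 2]), c(1, NA, 2))
  expect_equal(G$positions, c(100L, 200L, 300L))
  expect_equal(G$sample_ids, c("S1", "S2", "S3"))
})

test_that("multiallelic records are skipped with a warning", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"),
                      list("0/0\t0/1\t1/1", "0/1\t1/2\t2/2"),
                      alt = c("T", "T,G"))
  expect_warning(G <- read_vcf(f), "multiallelic")
  expect_equal(ncol(G$dosages), 1L)
})

test_that("a genotype matrix round-trips through VCF before imputation", {
  set.seed(11)
  d <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 5, 8)
  while (all(is.na(d))) d <- matrix(sample(c(0:2, NA), 40, TRUE), 5, 8)
  G <- genotype_matrix(d, paste0("S", 1:5), paste0("v", 1:8), "3",
                       seq(10L, by = 10L, length.out = 8L))
  f <- tempfile(fileext = ".vcf")
  write_vcf(G, f)
  G2 <- read_vcf(f)
  expect_equal(unname(G2$dosages), unname(G$dosages))
  expect_equal(G2$positions, G$positions)
  expect_equal(G2$sample_ids, G$sample_ids)
})

test_that("fold_and_qc folds major-allele coding, drops monomorphic, imputes", {
  d <- cbind(a = c(2, 2, 2, 1),   # coded-allele freq 7/8: fold
             b = c(0, 0, 0, 0),   # monomorphic: drop
             c = c(0, 2, NA, 1))  # impute NA with observed mean 1
  G <- genotype_matrix(d, paste0("S", 1:4), c("a", "b", "c"), "3",
                       c(10L, 20L, 30L))
  Gq <- fold_and_qc(G)
  expect_equal(Gq$variant_ids, c("a", "c"))
  expect_equal(unname(Gq$dosages[, 1]), c(0, 0, 0, 1))
  expect_equal(Gq$maf[1], 1 / 8)
  expect_equal(unname(Gq$dosages[, 2]), c(0, 2, 1, 1))
  expect_equal(Gq$maf[2], mean(c(0, 2, 1)) / 2)
  expect_false(anyNA(Gq$dosages))
})

test_that("fold_and_qc errors when everything is monomorphic", {
  G <- genotype_matrix(matrix(2, 4, 2), paste0("S", 1:4), c("a", "b"),
                       "3", c(1L, 2L))
  expect_error(fold_and_qc(G), "monomorphic")
})

test_that("folding is idempotent", {
  for (s in 1:5) {
    set.seed(s)
    d <- matrix(sample(c(0:2, NA), 60, replace = TRUE,
                       prob = c(.2, .2, .5, .1)), 10, 6)
    G <- genotype_matrix(d, paste0("S", 1:10), paste0("v", 1:6), "3",
                         1:6 * 10L)
    G1 <- tryCatch(fold_and_qc(G), error = function(e) NULL)
    if (is.null(G1)) next
    G2 <- fold_and_qc(G1)
    expect_equal(G2$dosages, G1$dosages)
    expect_equal(G2$maf, G1$maf)
  }
})

test_that("read_phenotypes selects trait and covariates and drops incomplete rows", {
  df <- data.frame(id = paste0("S", 1:5), SBP = c(120, 145, 130, 150, 118),
                   DBP = c(80, 92, 85, 95, 76), MED = c(0, 0, 1, 0, 0),
                   AGE = c(30, 40, NA, 60, 25), SEX = c(0, 1, 0, 1, 1))
  f <- toy_phenofile(tempfile(fileext = ".tsv"), df)
  expect_warning(P <- read_phenotypes(f, "SBP", c("AGE", "SEX")),
                 "dropping 1")
  expect_equal(length(P$y), 4L)
  expect_equal(P$sample_ids, paste0("S", c(1, 2, 4, 5)))
  expect_equal(P$covariate_names, c("AGE", "SEX"))
  # comma-separated variant parses identically
  f2 <- toy_phenofile(tempfile(fileext = ".csv"), df[-3, ], sep = ",")
  P2 <- read_phenotypes(f2, "SBP", c("AGE", "SEX"))
  expect_equal(P2$y, P$y)
})

test_that("read_phenotypes errors on absent trait column or empty file", {
  df <- data.frame(id = "S1", SBP = 120)
  f <- toy_phenofile(tempfile(fileext = ".tsv"), df)
  expect_error(read_phenotypes(f, "DBP"), "absent")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(character(0), f2)
  expect_error(read_phenotypes(f2, "SBP"), "empty")
})

test_that("build_gene_map honors the coordinate convention", {
  G <- genotype_matrix(matrix(1, 2, 3), c("S1", "S2"),
                       c("v1", "v2", "v3"), "3", c(100L, 150L, 250L))
  bed <- data.frame(gene = c("gA", "gB"), chrom = "3",
                    start = c(99L, 100L), end = c(100L, 200L))
  gm <- build_gene_map(bed, G, convention = "bed0")
  # BED [99,100) covers 1-based position 100 only
  expect_equal(gm$gA, 1L)
  # BED [100,200) covers positions 101..200: v2 only
  expect_equal(gm$gB, 2L)
  cl <- data.frame(gene = c("gA", "gB"), chrom = "3",
                   start = c(100L, 100L), end = c(150L, 260L))
  gm2 <- build_gene_map(cl, G, convention = "closed1")
  expect_equal(gm2$gA, c(1L, 2L))
  # overlapping genes share variants
  expect_equal(gm2$gB, c(1L, 2L, 3L))
  expect_error(build_gene_map(bed, G, convention = "halfopen"))
})

test_that("sample alignment is an explicit join and order-stable", {
  X <- toy_dosages(6, 3, seed = 2)
  G <- genotype_matrix(X, paste0("S", 1:6), colnames(X), "3", 1:3 * 10L)
  P <- phenotype_table(paste0("S", c(5, 3, 1, 6, 9)), c(1, 2, 3, 4, 5),
                       cbind(age = c(50, 40, 30, 60, 70)))
  al <- align_samples(G, P)
  expect_equal(al$G$sample_ids, paste0("S", c(1, 3, 5, 6)))
  expect_equal(al$P$y, c(3, 2, 1, 4))
  expect_equal(unname(al$G$dosages), unname(X[c(1, 3, 5, 6), ]))
  # shuffling the phenotype rows does not change the aligned arrays
  sh <- sample(5)
  P2 <- phenotype_table(P$sample_ids[sh], P$y[sh],
                        P$covariates[sh, , drop = FALSE])
  al2 <- align_samples(G, P2)
  expect_equal(al2$P$y, al$P$y)
  expect_equal(al2$G$dosages, al$G$dosages)
  expect_error(align_samples(G, phenotype_table("ZZ", 1)), "shared")
})
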