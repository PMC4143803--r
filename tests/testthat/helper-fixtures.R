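# Fixtures built in code: tiny VCF / phenotype files and toy genotype
# matrices used across the unit tests.

write_test_vcf <- function(path, gt_rows, chrom = "3",
                           pos = NULL, ids = NULL, alt = NULL,
                           samples = NULL) {
  p <- length(gt_rows)
  n <- length(strsplit(gt_rows[[1]], "\t")[[1]])
  samples <- samples %||% paste0("S", seq_len(n))
  pos <- pos %||% seq(100L, by = 100L, length.out = p)
  ids <- ids %||% paste0("v", seq_len(p))
  alt <- alt %||% rep("T", p)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(seq_len(p), function(j)
      paste(chrom, pos[j], ids[j], "A", alt[j], ".", "PASS", ".", "GT",
            gt_rows[[j]], sep = "\t"), character(1)))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n x p dosage matrix with moderate MAFs (guaranteed polymorphic columns)
toy_dosages <- function(n, p, seed, maf_range = c(0.1, 0.4)) {
  set.seed(seed)
  maf <- runif(p, maf_range[1], maf_range[2])
  X <- vapply(maf, function(m) rbinom(n, 2, m), numeric(n))
  while (any(apply(X, 2, var) == 0)) {
    j <- which(apply(X, 2, var) == 0)
    X[, j] <- vapply(maf[j], function(m) rbinom(n, 2, m),
                     numeric(n))
  }
  colnames(X) <- paste0("v", seq_len(p))
  X
}

toy_phenofile <- function(path, df, sep = "\t") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
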