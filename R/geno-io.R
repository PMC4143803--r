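# Genotype / phenotype / gene-map I-O and the internal data model.
#
# Genotypes are held as an n x p minor-allele dosage matrix (0/1/2, NA
# allowed before imputation) with per-variant metadata. All downstream tests
# assume fold_and_qc() has been applied: coded-allele frequency <= 0.5, no
# missing entries, no monomorphic variants.

#' Construct a genotype matrix object
#'
#' @param dosages n x p numeric matrix of allele counts in \{0, 1, 2\}
#'   (NA allowed before imputation); rows are samples, columns variants.
#' @param sample_ids length-n character vector.
#' @param variant_ids length-p character vector.
#' @param chrom length-p chromosome labels.
#' @param positions length-p 1-based chromosomal coordinates.
#' @param maf optional length-p minor-allele frequencies; recomputed from the
#'   observed entries when omitted.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, variant_ids, chrom, positions,
                            maf = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); p <- ncol(dosages)
  stopifnot(length(sample_ids) == n, length(variant_ids) == p,
            length(positions) == p, length(chrom) %in% c(1L, p))
  if (length(chrom) == 1L) chrom <- rep(chrom, p)
  bad <- !is.na(dosages) & !(dosages %in% 0:2) & (dosages < 0 | dosages > 2)
  if (any(bad)) input_error("dosages must lie in [0, 2]")
  if (is.null(maf)) maf <- colMeans(dosages, na.rm = TRUE) / 2
  dimnames(dosages) <- list(sample_ids, variant_ids)
  structure(list(dosages = dosages,
                 sample_ids = as.character(sample_ids),
                 variant_ids = as.character(variant_ids),
                 chrom = as.character(chrom),
                 positions = as.integer(positions),
                 maf = as.numeric(maf)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  missing entries: %d; MAF range: [%.4g, %.4g]\n",
              sum(is.na(x$dosages)),
              suppressWarnings(min(x$maf)), suppressWarnings(max(x$maf))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read a VCF file into a genotype matrix
#'
#' Parses biallelic SNV records of a VCF 4.x file into ALT-allele dosages
#' (minor-allele coding is applied later by [fold_and_qc()]). Multiallelic
#' records are skipped with a warning; missing genotypes (`./.`) become NA.
#'
#' @param path path to an uncompressed or gzipped VCF with a GT field.
#' @return a [genotype_matrix()] with pre-folding ALT dosages.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) input_error("VCF not found: %s", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    input_error("malformed VCF '%s': %s", path, conditionMessage(e)))
  if (nrow(vcf@fix) == 0L) input_error("VCF '%s' contains no records", path)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    warning(sprintf("skipping %d multiallelic record(s) in %s", sum(!bi), path))
    vcf <- vcf[bi, ]
  }
  if (nrow(vcf@fix) == 0L) input_error("VCF '%s': no biallelic records", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # allele dosage = number of ALT alleles in the GT string ("0/1", "1|1", ...)
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    out[ok] <- vapply(strsplit(g[ok], "[/|]"),
                      function(a) sum(a == "1"), numeric(1))
    out
  }
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))  # samples x variants
  for (j in seq_len(nrow(gt))) dos[, j] <- count_alt(gt[j, ])
  fix <- vcf@fix
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(dos,
                  sample_ids = colnames(gt),
                  variant_ids = ids,
                  chrom = fix[, "CHROM"],
                  positions = as.integer(fix[, "POS"]))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only genotypes. Integer dosages are written
#' as unphased genotypes (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.), so a
#' pre-imputation matrix round-trips exactly through [read_vcf()].
#'
#' @param G a [genotype_matrix()]; dosages must be integral or NA.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  d <- G$dosages
  if (any(!is.na(d) & d != round(d)))
    input_error("write_vcf requires integral (pre-imputation) dosages")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=rpls",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", G$sample_ids), collapse = "\t"))
  p <- ncol(d)
  rows <- vapply(seq_len(p), function(j) {
    g <- ifelse(is.na(d[, j]), "./.", gt_code[as.character(d[, j])])
    paste(c(G$chrom[j], G$positions[j], G$variant_ids[j], "A", "T", ".",
            "PASS", ".", "GT", g), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Fold to minor-allele coding, drop monomorphic variants, impute missing
#'
#' Variants whose coded-allele frequency (computed over observed entries)
#' exceeds 0.5 are recoded x -> 2 - x so dosages count the minor allele;
#' monomorphic variants are removed; remaining missing entries are replaced
#' by the per-variant mean dosage of the observed entries. The stored MAF is
#' computed from observed entries only. The operation is idempotent.
#'
#' @param G a [genotype_matrix()].
#' @return a QC'd [genotype_matrix()] with no missing entries and all
#'   frequencies in (0, 0.5].
#' @export
fold_and_qc <- function(G) {
  d <- G$dosages
  af <- colMeans(d, na.rm = TRUE) / 2
  flip <- !is.nan(af) & af > 0.5
  d[, flip] <- 2 - d[, flip]
  maf <- ifelse(flip, 1 - af, af)
  obs_var <- apply(d, 2L, function(x) stats::var(x[!is.na(x)]))
  keep <- !is.nan(maf) & maf > 0 & !is.na(obs_var) & obs_var > 0
  if (!any(keep)) input_error("all variants monomorphic after QC")
  if (any(!keep))
    log_msg("fold_and_qc: dropping %d monomorphic variant(s)", sum(!keep))
  d <- d[, keep, drop = FALSE]
  maf <- maf[keep]
  # mean imputation from observed entries of the folded column
  for (j in which(colSums(is.na(d)) > 0L)) {
    miss <- is.na(d[, j])
    d[miss, j] <- mean(d[!miss, j])
  }
  genotype_matrix(d, G$sample_ids, G$variant_ids[keep], G$chrom[keep],
                  G$positions[keep], maf = maf)
}

#' Construct a phenotype table
#'
#' @param sample_ids length-n identifiers.
#' @param y length-n trait values (numeric; binary traits coded 0/1).
#' @param covariates n x q numeric matrix (or NULL for no covariates).
#' @param covariate_names optional column names for `covariates`.
#' @return an object of class `phenotype_table`.
#' @export
phenotype_table <- function(sample_ids, y, covariates = NULL,
                            covariate_names = NULL) {
  n <- length(sample_ids)
  stopifnot(length(y) == n)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (!is.null(covariate_names)) colnames(covariates) <- covariate_names
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
  }
  structure(list(sample_ids = as.character(sample_ids),
                 y = as.numeric(y),
                 covariates = covariates,
                 covariate_names = colnames(covariates)),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples, %d covariate(s)\n",
              length(x$y), if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}

#' Read a delimited phenotype/covariate file
#'
#' Expects a header row and one row per sample; the delimiter (tab, comma,
#' or whitespace) is sniffed from the header line. Rows with a missing trait
#' or covariate value are dropped with a logged count.
#'
#' @param path file path.
#' @param trait_name column to use as the trait.
#' @param covariate_names columns to use as covariates (may be empty).
#' @param id_col sample-id column (default first column).
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, trait_name, covariate_names = character(),
                            id_col = NULL) {
  if (!file.exists(path)) input_error("phenotype file not found: %s", path)
  head_lines <- readLines(path, n = 50L)
  head_lines <- head_lines[!startsWith(head_lines, "#")]
  if (length(head_lines) == 0L) input_error("phenotype file '%s' is empty", path)
  first <- head_lines[1L]
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) input_error("phenotype file '%s' has no data rows", path)
  id_col <- id_col %||% names(df)[1L]
  for (col in c(id_col, trait_name, covariate_names))
    if (!col %in% names(df))
      input_error("column '%s' absent from %s", col, path)
  need <- df[, c(trait_name, covariate_names), drop = FALSE]
  complete <- stats::complete.cases(need)
  if (any(!complete)) {
    warning(sprintf("dropping %d row(s) with missing trait/covariates",
                    sum(!complete)))
    df <- df[complete, , drop = FALSE]
  }
  if (nrow(df) == 0L) input_error("no complete phenotype rows in %s", path)
  covs <- if (length(covariate_names))
    as.matrix(df[, covariate_names, drop = FALSE]) else NULL
  phenotype_table(df[[id_col]], df[[trait_name]], covs, covariate_names)
}

#' Align a genotype matrix and phenotype table on sample ids
#'
#' Performs an explicit inner join on sample ids; the output sample order is
#' the order of the shared ids as they appear in the genotype matrix, so the
#' aligned arrays are identical whichever object is subset first.
#'
#' @param G a [genotype_matrix()].
#' @param P a [phenotype_table()].
#' @return list with elements `G` and `P`, row-aligned.
#' @export
align_samples <- function(G, P) {
  common <- G$sample_ids[G$sample_ids %in% P$sample_ids]
  if (length(common) == 0L) input_error("no shared sample ids")
  gi <- match(common, G$sample_ids)
  pi <- match(common, P$sample_ids)
  Ga <- genotype_matrix(G$dosages[gi, , drop = FALSE], common, G$variant_ids,
                        G$chrom, G$positions, G$maf)
  Pa <- phenotype_table(common, P$y[pi],
                        if (is.null(P$covariates)) NULL
                        else P$covariates[pi, , drop = FALSE],
                        P$covariate_names)
  list(G = Ga, P = Pa)
}

#' Assign variants to genes by interval overlap
#'
#' Builds a gene -> ordered-variant-index map from a table of gene intervals.
#' Input intervals may use BED convention (0-based half-open) or 1-based
#' closed coordinates; they are converted to the package's internal 1-based
#' closed convention at this boundary. A variant may fall in several
#' overlapping genes; within each gene, indices are ordered by position.
#'
#' @param intervals data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @param G a [genotype_matrix()].
#' @param convention `"bed0"` (0-based half-open) or `"closed1"`
#'   (1-based closed).
#' @return named list of integer variant-index vectors, class `gene_map`.
#' @export
build_gene_map <- function(intervals, G, convention = c("bed0", "closed1")) {
  convention <- match.arg(convention)
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(intervals)))
  start1 <- if (convention == "bed0") intervals$start + 1L else intervals$start
  end1 <- intervals$end  # closed right end in both conventions after shift
  ok <- start1 <= end1
  gr_genes <- GenomicRanges::GRanges(
    seqnames = as.character(intervals$chrom)[ok],
    ranges = IRanges::IRanges(start = start1[ok], end = end1[ok]))
  gr_var <- GenomicRanges::GRanges(
    seqnames = G$chrom,
    ranges = IRanges::IRanges(start = G$positions, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_var, gr_genes)
  gene_of_hit <- as.character(intervals$gene)[ok][S4Vectors::subjectHits(hits)]
  idx_of_hit <- S4Vectors::queryHits(hits)
  gm <- lapply(split(idx_of_hit, gene_of_hit), function(i) {
    i <- unique(i)
    i[order(G$positions[i])]
  })
  # keep the gene order of the input table; genes with no variants are kept
  # as empty entries so truth tables stay aligned with the map
  genes <- unique(as.character(intervals$gene))
  out <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) out[[g]] <- gm[[g]] %||% integer(0)
  structure(out, class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("gene_map: %d genes; variants per gene: min %d, median %g, max %d\n",
              length(x), if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) stats::median(sizes) else 0,
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}
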