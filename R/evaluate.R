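# Aggregation of per-gene, per-replicate decisions into power, type-I
# error, and accuracy summaries.
#
# Definitions: a gene is "detected" in a replicate iff its p-value <= alpha
# (raw per-gene p-values, no multiple-testing correction, inclusive
# threshold). Power of a causal gene = detections / replicates. Type-I
# error = total false positives / (noncausal genes x replicates). Accuracy
# of one replicate = (TP + TN) / all gene decisions. Method failures count
# as non-detections (p = 1, flagged), never as dropped genes, so
# denominators are stable.

#' Per-gene power from detection counts
#' @param detections number of replicates in which the gene was detected.
#' @param n_replicates total replicates.
#' @return detection fraction in [0, 1].
#' @export
power_single_gene <- function(detections, n_replicates) {
  if (n_replicates <= 0) input_error("n_replicates must be positive")
  stopifnot(detections >= 0, detections <= n_replicates)
  detections / n_replicates
}

#' Type-I error across noncausal genes
#' @param false_positives_total total significant noncausal gene decisions.
#' @param n_noncausal number of noncausal genes.
#' @param n_replicates number of replicates.
#' @return false-positive fraction in [0, 1].
#' @export
type1_across_genes <- function(false_positives_total, n_noncausal,
                               n_replicates) {
  if (n_noncausal <= 0 || n_replicates <= 0)
    input_error("denominator counts must be positive")
  stopifnot(false_positives_total >= 0)
  false_positives_total / (n_noncausal * n_replicates)
}

#' Accuracy of one replicate's gene decisions
#' @param tp,fn true positives and false negatives (causal genes).
#' @param fp,tn false positives and true negatives (noncausal genes).
#' @return (TP + TN) / (TP + FN + FP + TN).
#' @export
accuracy_single_replicate <- function(tp, fn, fp, tn) {
  tot <- tp + fn + fp + tn
  if (tot <= 0) input_error("accuracy undefined for all-zero counts")
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  (tp + tn) / tot
}

method_label <- function(m) {
  switch(tolower(m), rpls = "rPLS", sum = "SUM", skat = "SKAT",
         skato = , `skat-o` = "SKAT-O",
         input_error("unknown method '%s'", m))
}

#' Run the gene-based tests over all genes for one phenotype
#'
#' Applies the requested methods gene by gene. The SKAT/SKAT-O null model
#' is fitted once per phenotype and shared across genes. A method failure
#' on a gene is recorded as p = 1 with a flag and the run continues.
#'
#' @param G a QC'd [genotype_matrix()].
#' @param gene_map a `gene_map` of variant indices into `G`.
#' @param y length-n trait.
#' @param Z optional covariate matrix.
#' @param family `"gaussian"` or `"binomial"`.
#' @param methods subset of `c("rpls", "sum", "skat", "skato")`.
#' @param config an [rpls_config()] for the rPLS runs.
#' @param weights_beta SKAT MAF-weight shape parameters.
#' @return data.frame with columns gene, method, p_value, k, top_snv, flags.
#' @export
run_gene_tests <- function(G, gene_map, y, Z = NULL,
                           family = c("gaussian", "binomial"),
                           methods = c("rpls", "sum", "skat", "skato"),
                           config = rpls_config(),
                           weights_beta = c(1, 25)) {
  family <- match.arg(family)
  methods <- vapply(methods, method_label, character(1))
  nm <- if (any(methods %in% c("SKAT", "SKAT-O")))
    skat_null_model(y, Z, family) else NULL
  rows <- list()
  for (g in names(gene_map)) {
    idx <- gene_map[[g]]
    Xg <- G$dosages[, idx, drop = FALSE]
    for (m in methods) {
      row <- tryCatch({
        if (length(idx) == 0L) {
          list(p = 1, k = 0L, top = NA_character_, flags = "empty_gene")
        } else if (m == "rPLS") {
          fit <- rpls_test(Xg, y, Z, family = family, config = config,
                           variant_ids = G$variant_ids[idx],
                           positions = G$positions[idx])
          list(p = fit$p_value, k = fit$k,
               top = if (fit$k > 0L) fit$snv_ranking[1L] else NA_character_,
               flags = fit$flags)
        } else if (m == "SUM") {
          r <- sum_test(Xg, y, Z, family)
          list(p = r$p_value, k = length(idx), top = NA_character_,
               flags = r$flags)
        } else if (m == "SKAT") {
          r <- skat_test(Xg, maf = G$maf[idx], family = family,
                         weights_beta = weights_beta, null_model = nm)
          list(p = r$p_value, k = length(idx), top = NA_character_,
               flags = r$flags)
        } else {
          r <- skat_o_test(Xg, maf = G$maf[idx], family = family,
                           weights_beta = weights_beta, null_model = nm)
          list(p = r$p_value, k = length(idx), top = NA_character_,
               flags = r$flags)
        }
      }, error = function(e) list(p = 1, k = NA_integer_,
                                  top = NA_character_,
                                  flags = paste0("error:",
                                                 conditionMessage(e))))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, method = m, p_value = row$p, k = row$k,
        top_snv = row$top, flags = row$flags, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Benchmark the methods over a replicate set
#'
#' QCs the fixed genotypes, re-runs every requested method on every
#' phenotype replicate, thresholds p-values at `alpha`, and aggregates the
#' decisions into per-method power, type-I error, and accuracy, plus
#' per-gene detection counts.
#'
#' @param replicates a `replicate_set` from [simulate_phenotypes()].
#' @param methods subset of `c("rpls", "sum", "skat", "skato")`.
#' @param alpha nominal per-gene significance threshold.
#' @param config an [rpls_config()]; its seed drives the CV folds.
#' @param Z optional covariate matrix overriding the simulated age/sex.
#' @return object of class `evaluation_summary`: data.frame `summary`
#'   (method, trait, alpha, power, type1, accuracy), matrix
#'   `per_gene_counts` (gene x method detection counts), and the decision
#'   table `detections`.
#' @export
run_benchmark <- function(replicates, methods = c("rpls", "sum", "skat",
                                                  "skato"),
                          alpha = 0.001, config = rpls_config(), Z = NULL) {
  stopifnot(inherits(replicates, "replicate_set"))
  methods <- vapply(methods, method_label, character(1))
  family <- if (replicates$config$trait_model == "gaussian")
    "gaussian" else "binomial"
  G <- fold_and_qc(replicates$genotype)
  gm <- sim_gene_map(G)
  # genes whose variants were all dropped by QC keep empty entries so that
  # truth denominators stay fixed
  for (g in names(replicates$truth))
    if (is.null(gm[[g]])) gm[[g]] <- integer(0)
  gm <- structure(gm[names(replicates$truth)], class = "gene_map")
  Z <- Z %||% replicates$covariates
  R <- ncol(replicates$phenotypes)
  truth <- replicates$truth
  counts <- matrix(0L, length(truth), length(methods),
                   dimnames = list(names(truth), methods))
  acc <- matrix(NA_real_, R, length(methods),
                dimnames = list(NULL, methods))
  keep_rows <- vector("list", R)
  for (r in seq_len(R)) {
    y <- replicates$phenotypes[, r]
    res <- run_gene_tests(G, gm, y, Z, family = family,
                          methods = tolower(sub("-", "", methods)),
                          config = config)
    det <- res$p_value <= alpha
    for (m in methods) {
      mi <- res$method == m
      counts[res$gene[mi & det], m] <- counts[res$gene[mi & det], m] + 1L
      tp <- sum(det[mi] & truth[res$gene[mi]])
      fp <- sum(det[mi] & !truth[res$gene[mi]])
      acc[r, m] <- accuracy_single_replicate(
        tp, sum(truth) - tp, fp, sum(!truth) - fp)
    }
    keep_rows[[r]] <- cbind(replicate = r, res)
  }
  summary <- do.call(rbind, lapply(methods, function(m) {
    data.frame(method = m, trait = replicates$config$trait_model,
               alpha = alpha,
               power = mean(counts[truth, m] / R),
               type1 = type1_across_genes(sum(counts[!truth, m]),
                                          sum(!truth), R),
               accuracy = mean(acc[, m]), stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, per_gene_counts = counts,
                 detections = do.call(rbind, keep_rows),
                 alpha = alpha, n_replicates = R, truth = truth),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("evaluation_summary: %d replicates, alpha = %g\n",
              x$n_replicates, x$alpha))
  s <- x$summary
  s$power <- sprintf("%.2f%%", 100 * s$power)
  s$type1 <- sprintf("%.3f%%", 100 * s$type1)
  s$accuracy <- sprintf("%.2f%%", 100 * s$accuracy)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation summary as a tidy TSV
#'
#' @param summary an `evaluation_summary`.
#' @param path output path.
#' @param provenance optional named list recorded in `#`-comment header
#'   lines (seed, config hash, ...).
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path, provenance = list()) {
  stopifnot(inherits(summary, "evaluation_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  utils::write.table(summary$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

provenance_header <- function(provenance = list()) {
  base <- list(tool = paste0("rpls ", as.character(
    utils::packageVersion("rpls"))))
  prov <- c(base, provenance)
  vapply(names(prov), function(k) sprintf("# %s: %s", k, prov[[k]]),
         character(1))
}
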