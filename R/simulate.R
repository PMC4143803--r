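# Replicate-based synthetic data generator.
#
# Emulates the evaluation design of sequencing-panel simulation studies:
# genotypes are drawn once and held fixed, phenotypes are re-simulated many
# times from a known generating model, and every gene carries a known causal
# flag. The allele-frequency spectrum is severely skewed toward rare
# alleles (MAF ~ min(Beta(0.2, 5), 0.5) by default); causal genes may mix
# positive and negative effects, the setting where same-direction burden
# tests fail.

#' Specification of one simulated gene
#'
#' @param gene_name character name.
#' @param p_snvs number of variants in the gene.
#' @param causal_idx indices (into 1..p_snvs) of causal variants; empty for
#'   a noncausal gene.
#' @param effect_sizes signed per-allele effects (trait-sd units), one per
#'   causal variant.
#' @param causal_maf optional MAFs to pin for the causal variants (others
#'   are drawn from the spectrum).
#' @return list of class `gene_spec`.
#' @export
gene_spec <- function(gene_name, p_snvs, causal_idx = integer(0),
                      effect_sizes = numeric(0), causal_maf = NULL) {
  stopifnot(length(causal_idx) == length(effect_sizes),
            all(causal_idx >= 1L & causal_idx <= p_snvs))
  if (!is.null(causal_maf))
    stopifnot(length(causal_maf) == length(causal_idx))
  structure(list(gene_name = as.character(gene_name),
                 p_snvs = as.integer(p_snvs),
                 causal_idx = as.integer(causal_idx),
                 effect_sizes = as.numeric(effect_sizes),
                 causal_maf = causal_maf),
            class = "gene_spec")
}

#' Simulation configuration
#'
#' Defaults mirror the study design the package evaluates: 142 unrelated
#' samples, 200 phenotype replicates over fixed genotypes, a rare-skewed
#' Beta(0.2, 5) MAF spectrum truncated at 0.5, age and sex covariates, and
#' traits in standardized units (noise sd 1).
#'
#' @param genes list of [gene_spec()] objects.
#' @param n_samples number of samples.
#' @param n_replicates number of phenotype replicates.
#' @param maf_spectrum list with `shape1`, `shape2`, `max`.
#' @param noise_sd residual sd of the quantitative trait.
#' @param covariate_effects named vector with elements `age` and `sex`
#'   (per-year and male-female effects in trait-sd units).
#' @param trait_model `"gaussian"`, `"liability"` (binary via a liability
#'   threshold), or `"htn"` (correlated SBP/DBP in mm Hg plus a medication
#'   flag, dichotomized by [derive_htn()]).
#' @param prevalence case fraction targeted by the liability threshold.
#' @param ld_rho AR(1) correlation of the latent Gaussian copula inducing
#'   within-gene LD (0 = independent variants, the default).
#' @param beta0 trait intercept.
#' @param seed root seed; all draws flow from named substreams of it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(genes, n_samples = 142L, n_replicates = 200L,
                              maf_spectrum = list(shape1 = 0.2, shape2 = 5,
                                                  max = 0.5),
                              noise_sd = 1, covariate_effects = c(age = 0.03,
                                                                  sex = 0.2),
                              trait_model = c("gaussian", "liability", "htn"),
                              prevalence = 0.3, ld_rho = 0, beta0 = 0,
                              seed = 1L) {
  trait_model <- match.arg(trait_model)
  stopifnot(length(genes) >= 1L,
            all(vapply(genes, inherits, logical(1), "gene_spec")))
  nm <- vapply(genes, `[[`, character(1), "gene_name")
  if (anyDuplicated(nm)) input_error("duplicate gene names in scenario")
  structure(list(genes = genes, n_samples = as.integer(n_samples),
                 n_replicates = as.integer(n_replicates),
                 maf_spectrum = maf_spectrum, noise_sd = noise_sd,
                 covariate_effects = covariate_effects,
                 trait_model = trait_model, prevalence = prevalence,
                 ld_rho = ld_rho, beta0 = beta0, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw fixed genotypes for a scenario
#'
#' Per variant, a MAF is drawn from the configured spectrum (causal-variant
#' MAFs may be pinned by the gene spec); dosages are Binomial(2, maf) under
#' Hardy-Weinberg equilibrium, independently across variants unless
#' `ld_rho > 0`, in which case a latent Gaussian AR(1) copula induces
#' within-gene LD. Variant ids are `<gene>:v<j>`; genes occupy disjoint
#' 1-Mb windows on one chromosome.
#'
#' @param config a [simulation_config()].
#' @return a [genotype_matrix()] (pre-QC: monomorphic columns possible).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  sp <- config$maf_spectrum
  with_seed(substream_seed(config$seed, "genotypes"), {
    per_gene <- lapply(seq_along(config$genes), function(g) {
      gs <- config$genes[[g]]
      p <- gs$p_snvs
      maf <- draw_maf_spectrum(p, sp)
      if (!is.null(gs$causal_maf)) maf[gs$causal_idx] <- gs$causal_maf
      if (config$ld_rho > 0) {
        z <- matrix(stats::rnorm(n * p), n, p)
        if (p > 1L)
          for (j in 2:p)
            z[, j] <- config$ld_rho * z[, j - 1L] +
              sqrt(1 - config$ld_rho^2) * z[, j]
        d <- stats::qbinom(stats::pnorm(z), 2L,
                           matrix(maf, n, p, byrow = TRUE))
      } else {
        d <- matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), n, p)
      }
      list(d = d, maf = maf,
           ids = paste0(gs$gene_name, ":v", seq_len(p)),
           pos = (g - 1L) * 1000000L + seq_len(p) * 10L)
    })
    genotype_matrix(do.call(cbind, lapply(per_gene, `[[`, "d")),
                    sample_ids = paste0("S", seq_len(n)),
                    variant_ids = unlist(lapply(per_gene, `[[`, "ids")),
                    chrom = "3",
                    positions = unlist(lapply(per_gene, `[[`, "pos")))
  })
}

# MAF draw from the configured spectrum: Beta(shape1, shape2) truncated
# at `max` (minor-allele frequencies cannot exceed 0.5)
draw_maf_spectrum <- function(p, spectrum) {
  pmin(stats::rbeta(p, spectrum$shape1, spectrum$shape2), spectrum$max)
}

#' Gene map implied by simulated variant ids
#'
#' Recovers the gene -> variant-index map from the `<gene>:v<j>` naming of
#' simulated variants; valid on the raw or QC'd genotype matrix (indices
#' follow the matrix it is computed on).
#'
#' @param G a [genotype_matrix()] produced by [simulate_genotypes()]
#'   (possibly after [fold_and_qc()]).
#' @return a `gene_map`.
#' @export
sim_gene_map <- function(G) {
  gene <- sub(":v[0-9]+$", "", G$variant_ids)
  idx <- split(seq_along(gene), factor(gene, levels = unique(gene)))
  structure(lapply(idx, function(i) i[order(G$positions[i])]),
            class = "gene_map")
}

#' Simulate phenotype replicates over fixed genotypes
#'
#' Covariates (age ~ Uniform(20, 80), sex ~ Bernoulli(0.5)) are drawn once
#' and fixed with the genotypes. Per replicate, the quantitative trait is
#' y = beta0 + sum causal effects * dosage + gamma_age age + gamma_sex sex
#' + N(0, noise_sd^2) noise. A `"liability"` trait thresholds that
#' liability at the configured prevalence; an `"htn"` trait builds
#' correlated SBP/DBP (mm Hg) sharing the genetic signal plus a medication
#' flag and applies [derive_htn()].
#'
#' @param G the [genotype_matrix()] from [simulate_genotypes()].
#' @param config the same [simulation_config()].
#' @return object of class `replicate_set`: `genotype`, `phenotypes`
#'   (n x n_replicates), `covariates` (age, sex), `truth` (named logical
#'   per gene), `config`; for `"htn"`, also `sbp`, `dbp`, `medication`.
#' @export
simulate_phenotypes <- function(G, config) {
  stopifnot(inherits(G, "genotype_matrix"),
            inherits(config, "simulation_config"))
  n <- nrow(G$dosages)
  R <- config$n_replicates
  cov_seed <- substream_seed(config$seed, "covariates")
  covs <- with_seed(cov_seed, cbind(age = stats::runif(n, 20, 80),
                                    sex = stats::rbinom(n, 1L, 0.5)))
  # genetic + covariate linear predictor, fixed across replicates
  lp <- rep(config$beta0, n)
  for (gs in config$genes) {
    if (length(gs$causal_idx) == 0L) next
    ids <- paste0(gs$gene_name, ":v", gs$causal_idx)
    j <- match(ids, G$variant_ids)
    ok <- !is.na(j)
    if (any(ok))
      lp <- lp + G$dosages[, j[ok], drop = FALSE] %*% gs$effect_sizes[ok]
  }
  lp <- as.numeric(lp) + covs %*% config$covariate_effects[c("age", "sex")]
  lp <- as.numeric(lp)
  eps <- with_seed(substream_seed(config$seed, "phenotypes"),
                   matrix(stats::rnorm(n * R, 0, config$noise_sd), n, R))
  liab <- lp + eps
  truth <- stats::setNames(
    vapply(config$genes, function(g) length(g$causal_idx) > 0L, logical(1)),
    vapply(config$genes, `[[`, character(1), "gene_name"))
  extra <- list()
  if (config$trait_model == "gaussian") {
    Y <- liab
  } else if (config$trait_model == "liability") {
    thr <- mean(lp) + stats::qnorm(1 - config$prevalence) *
      sqrt(stats::var(lp) + config$noise_sd^2)
    Y <- (liab > thr) * 1L
  } else {  # htn: correlated SBP/DBP sharing the genetic signal
    e2 <- with_seed(substream_seed(config$seed, "dbp_noise"),
                    matrix(stats::rnorm(n * R), n, R))
    med <- with_seed(substream_seed(config$seed, "medication"),
                     stats::rbinom(n, 1L, 0.15))
    sbp <- 120 + 15 * scale_to_sd1(liab)
    dbp <- 80 + 10 * (0.6 * scale_to_sd1(liab) + 0.8 * e2)
    Y <- matrix(0L, n, R)
    for (r in seq_len(R)) Y[, r] <- derive_htn(sbp[, r], dbp[, r], med)
    extra <- list(sbp = sbp, dbp = dbp, medication = med)
  }
  dimnames(Y) <- list(G$sample_ids, paste0("rep", seq_len(R)))
  structure(c(list(genotype = G, phenotypes = Y, covariates = covs,
                   truth = truth, config = config), extra),
            class = "replicate_set")
}

# standardize columns jointly by the overall sd (keeps replicate-to-
# replicate comparability of the mm Hg scale)
scale_to_sd1 <- function(m) (m - mean(m)) / stats::sd(as.numeric(m))

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf(
    "replicate_set: %d samples, %d variants, %d genes (%d causal), %d replicates, trait %s\n",
    nrow(x$phenotypes), ncol(x$genotype$dosages), length(x$truth),
    sum(x$truth), ncol(x$phenotypes), x$config$trait_model))
  invisible(x)
}

#' Default benchmark scenario
#'
#' A miniature of the evaluation design: 30 causal genes (half with
#' mixed-direction effects) and 100 noncausal genes of 50-500 variants
#' each, one "anchor" gene carrying a single dominant-effect variant (to
#' exercise loading-vector ranking), 142 samples, and 200 phenotype
#' replicates.
#'
#' @param seed root seed.
#' @param n_samples,n_replicates overrides for the scenario scale.
#' @return a [simulation_config()].
#' @export
default_scenario <- function(seed = 1L, n_samples = 142L,
                             n_replicates = 200L) {
  genes <- with_seed(substream_seed(seed, "scenario"), {
    out <- list(gene_spec("ANCHOR1", 100L, causal_idx = 50L,
                          effect_sizes = 1.0, causal_maf = 0.1))
    for (g in 2:30) {
      p <- sample(50:500, 1L)
      nc <- sample(2:8, 1L)
      idx <- sort(sample(seq_len(p), nc))
      mag <- stats::runif(nc, 0.2, 0.6)
      sgn <- if (g %% 2 == 0) sample(c(-1, 1), nc, replace = TRUE)
             else rep(1, nc)
      out[[g]] <- gene_spec(sprintf("CAUSAL%02d", g), p, idx, mag * sgn,
                            causal_maf = stats::runif(nc, 0.01, 0.3))
    }
    for (g in 1:100)
      out[[30L + g]] <- gene_spec(sprintf("NULL%03d", g),
                                  sample(50:500, 1L))
    out
  })
  simulation_config(genes, n_samples = n_samples,
                    n_replicates = n_replicates, seed = seed)
}

#' Write a scenario configuration to JSON
#' @param config a [simulation_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- unclass(config)
  x$genes <- lapply(config$genes, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, null = "null")
  invisible(path)
}

#' Read a scenario configuration from JSON
#' @param path JSON file written by [write_scenario()].
#' @return a [simulation_config()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) input_error("scenario file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  genes <- lapply(x$genes, function(g)
    gene_spec(g$gene_name, g$p_snvs,
              causal_idx = unlist(g$causal_idx) %||% integer(0),
              effect_sizes = unlist(g$effect_sizes) %||% numeric(0),
              causal_maf = if (length(unlist(g$causal_maf))) unlist(g$causal_maf)))
  simulation_config(genes,
                    n_samples = x$n_samples,
                    n_replicates = x$n_replicates,
                    maf_spectrum = x$maf_spectrum,
                    noise_sd = x$noise_sd,
                    covariate_effects = unlist(x$covariate_effects),
                    trait_model = x$trait_model,
                    prevalence = x$prevalence,
                    ld_rho = x$ld_rho,
                    beta0 = x$beta0,
                    seed = x$seed)
}
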