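# Analysis traits derived from raw blood-pressure measurements.

#' Trait specification
#'
#' Maps a trait name to its GLM family: the binary hypertension status (HTN)
#' uses the binomial family; SBP, DBP, and the PC1 composite are gaussian.
#'
#' @param name one of `"DBP"`, `"SBP"`, `"HTN"`, `"PC1"`.
#' @return list with elements `name` and `family`.
#' @export
trait_spec <- function(name = c("DBP", "SBP", "HTN", "PC1")) {
  name <- match.arg(name)
  list(name = name, family = if (name == "HTN") "binomial" else "gaussian")
}

#' Derive binary hypertension status
#'
#' A sample is a case (1) if SBP >= 140 mm Hg, DBP >= 90 mm Hg, or the
#' sample is on antihypertensive medication; thresholds are inclusive.
#' A hypertensive reading decides the status regardless of a missing
#' medication flag; when neither pressure reaches its threshold and the
#' flag is missing, the result is NA (such rows are dropped downstream).
#'
#' @param sbp systolic blood pressure, mm Hg.
#' @param dbp diastolic blood pressure, mm Hg.
#' @param on_medication logical (or 0/1) antihypertensive-medication flag.
#' @return integer vector of 0/1 (NA where undecidable).
#' @export
derive_htn <- function(sbp, dbp, on_medication) {
  stopifnot(length(sbp) == length(dbp), length(dbp) == length(on_medication))
  if (any(stats::na.omit(c(sbp, dbp)) < 0))
    input_error("blood pressures must be non-negative")
  med <- as.logical(on_medication)
  by_bp <- (!is.na(sbp) & sbp >= 140) | (!is.na(dbp) & dbp >= 90)
  out <- ifelse(by_bp, 1L, ifelse(is.na(med), NA_integer_, as.integer(med)))
  as.integer(out)
}

#' First principal component of SBP and DBP
#'
#' Standardizes each pressure column to mean 0, sd 1, and projects onto the
#' leading eigenvector of their 2 x 2 correlation matrix. The sign is fixed
#' so the SBP loading is positive (higher PC1 = higher blood pressure);
#' scores have mean 0. Standardizing first makes the composite invariant to
#' the units of either input.
#'
#' @param sbp_vec,dbp_vec numeric vectors, length n >= 3, non-constant.
#' @return numeric score vector with attributes `loadings` (named length-2
#'   unit vector) and `eigenvalue` (variance explained, out of 2).
#' @export
derive_pc1 <- function(sbp_vec, dbp_vec) {
  stopifnot(length(sbp_vec) == length(dbp_vec))
  if (length(sbp_vec) < 3L) input_error("derive_pc1 requires n >= 3")
  if (stats::sd(sbp_vec) == 0 || stats::sd(dbp_vec) == 0)
    input_error("derive_pc1: constant input column")
  z1 <- as.numeric(scale(sbp_vec))
  z2 <- as.numeric(scale(dbp_vec))
  r <- stats::cor(z1, z2)
  e <- eigen(matrix(c(1, r, r, 1), 2L), symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (v[1L] < 0) v <- -v
  scores <- z1 * v[1L] + z2 * v[2L]
  structure(scores,
            loadings = stats::setNames(v, c("SBP", "DBP")),
            eigenvalue = e$values[1L])
}
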