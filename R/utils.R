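# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from a single root seed; independent
#' stages (genotypes, phenotypes, CV folds, ...) draw from substreams derived
#' deterministically from the root seed and a stream name, so that changing
#' one stage's draws never perturbs another's.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 97) %% 2147483647)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers the user's random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Structured log line on stderr; results never go to stderr, logs never to
# stdout, so pipelines can consume output. Quiet unless the rpls.verbose
# option is set (the command-line wrapper sets it).
log_msg <- function(fmt, ...) {
  if (isTRUE(getOption("rpls.verbose", FALSE)))
    message(sprintf(paste0("[rpls] ", fmt), ...))
}

# Stable hash of an R object (via its canonical JSON) for provenance headers.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = 10, force = TRUE)
  unname(tools::md5sum(f))
}

# Error constructors: input errors (bad files, misaligned samples) map to CLI
# exit code 2, method/runtime errors to exit code 1.
input_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("rpls_input_error", "error")))
}
method_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("rpls_method_error", "error")))
}
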