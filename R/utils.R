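# Internal helpers shared across modules.

#' spatialTME: spatial tumour micro-environment analysis for IMC
#'
#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a parent seed and a character tag.
# Keeps all derived seeds in [0, 2^31 - 1] so they are valid R integers.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(tag)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Percentile by linear interpolation between order statistics (type 7),
# fixed across the package so test oracles are exact.
percentile <- function(x, q) {
  stats::quantile(x, probs = q / 100, type = 7, names = FALSE, na.rm = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
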