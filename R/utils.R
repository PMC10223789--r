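# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Column z-scoring with constant-column guard (sd 0 -> column left at 0).
zscore <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
  }
  scale[!is.finite(scale) | scale == 0] <- 1
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

msg <- function(...) message("[depnet] ", ...)

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
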