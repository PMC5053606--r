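# internal helpers

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
# seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# uniform draw among argmax positions (pseudocode everywhere is silent on
# ties; random tie-breaking keeps runs reproducible under a fixed seed)
which_max_random <- function(x) {
  m <- max(x)
  idx <- which(x >= m - 1e-12)
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

# sample() without the length-1 surprise
sample_vec <- function(x, size = length(x)) {
  if (length(x) <= 1L && size == length(x)) return(x)
  x[sample.int(length(x), size)]
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
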