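# Internal helpers: scoped seeding and deterministic seed streams.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream of `n` sub-seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(2147483646L, n, replace = (n > 2e6))))
}

# sample() without its length-1 surprise
resample <- function(x, size) x[sample.int(length(x), size)]

abort_classed <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

signal_degenerate_panel <- function(msg) {
  warning(structure(class = c("synthassoc_degenerate_panel", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / pmax(n, 1))
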