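# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without clobbering the caller's
# stream. All stochastic operations in the package funnel through this so
# that identical seeds give bit-identical output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Stage-specific seeds derived from one global seed; kept below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(genome = 11L, expression = 101L, counts = 211L,
               coverage = 307L, kinetics = 401L, qpcr = 503L,
               cluster = 601L, bootstrap = 701L, pipeline = 811L)
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  (as.integer(seed) * 7919L + off) %% 2147483562L
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
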