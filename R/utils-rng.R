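# RNG scoping helpers.  Every public stochastic operation takes an explicit
# `seed` argument; a non-NULL seed is applied locally and the caller's RNG
# state is restored on exit, so seeded calls never perturb the session stream.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage seed from a master seed and the stage name, so pipeline
# stages can be re-run independently with reproducible streams.  Kept below
# 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(master, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(master) + 7919 * h) %% 2147483629)
}
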