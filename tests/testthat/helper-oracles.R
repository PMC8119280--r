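# Independent oracles used across tests.  These are deliberately written
# with different algorithms from the package internals (lm() instead of the
# closed-form slope, exhaustive window enumeration, recursive flood fill,
# normal equations) so that agreement is evidence, not tautology.

# OLS slope via lm()
lm_slope <- function(d) {
  unname(stats::coef(stats::lm(d ~ x, data = data.frame(d = d, x = 0:4)))[2])
}

# Brute-force trial labeler: enumerates every window of `window` consecutive
# staircase trials per staircase via lm() and marks members of flat windows.
brute_force_at_threshold <- function(session, window = 5L, tol = 1e-9) {
  at <- rep(FALSE, nrow(session))
  for (id in c("A", "B")) {
    idx <- which(session$kind == "staircase" & session$staircase_id == id)
    d <- session$duration_units[idx]
    for (s in seq_len(length(idx) - window + 1L)) {
      dd <- d[s:(s + window - 1L)]
      if (abs(lm_slope(dd)) < tol) at[idx[s:(s + window - 1L)]] <- TRUE
    }
  }
  at
}

brute_force_categories <- function(session, at) {
  vapply(seq_len(nrow(session)), function(i) {
    k <- session$kind[i]; r <- session$response[i]
    if (k == "negative_control") return("OT")
    if (r == "none") return("OT")
    if (k == "positive_control") return(if (r == "yes") "SNT" else "OT")
    if (at[i]) { if (r == "yes") "ST" else "UT" }
    else { if (r == "yes") "SNT" else "UNT" }
  }, character(1))
}

# Recursive flood fill over a 3-D logical array (independent component
# labeller); returns sorted component sizes.
flood_fill_sizes <- function(bin, offsets) {
  d <- dim(bin)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  coords <- which(bin, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    c0 <- coords[r, ]
    if (seen[c0[1], c0[2], c0[3]]) next
    size <- 0L
    queue <- list(c0)
    seen[c0[1], c0[2], c0[3]] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(offsets))) {
        q <- p + offsets[k, ]
        if (any(q < 1) || any(q > d)) next
        if (bin[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

offsets_for <- function(connectivity) {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6" = o[rowSums(abs(o)) == 1, , drop = FALSE],
         "18" = o[rowSums(abs(o)) <= 2, , drop = FALSE],
         "26" = o)
}

# Tiny beta_maps builder for group-level tests: `vals` is a named list of
# 3-D arrays (one per condition).
fake_beta_maps <- function(vals, mask = NULL) {
  d <- dim(vals[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  structure(list(beta = vals, mask = mask, empty = character(0),
                 geometry = NULL),
            class = "beta_maps")
}

# An observer that always answers "yes" (deterministic).
always_yes_observer <- function() {
  observer(threshold_ms = 1e-6 + .Machine$double.eps, slope_ms = 1,
           lapse_rate = 0, guess_rate = 1 - 1e-12, no_response_rate = 0)
}
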