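test_that("window_slope agrees with lm() on characteristic windows", {
  expect_equal(window_slope(rep(7, 5)), 0)
  expect_equal(window_slope(c(5, 4, 5, 4, 5)), lm_slope(c(5, 4, 5, 4, 5)))
  expect_equal(window_slope(c(5, 4, 5, 4, 5)), 0)
  expect_equal(window_slope(c(400, 330, 260, 190, 120)), -70)
  expect_equal(window_slope(c(400, 330, 260, 190, 120)),
               lm_slope(c(400, 330, 260, 190, 120)))
  set.seed(4)
  for (k in 1:10) {
    d <- rnorm(5)
    expect_equal(window_slope(d), lm_slope(d), tolerance = 1e-10)
  }
  expect_error(window_slope(1:4), "length 5")
})

make_manual_session <- function(units_a, resp_a, units_b = units_a,
                                resp_b = resp_a, catch_at = NULL) {
  # hand-built session: interleave A, B, then append catch trials at given
  # positions (defaults to the end)
  na <- length(units_a); nb <- length(units_b)
  df <- rbind(
    data.frame(kind = "staircase", staircase_id = "A",
               duration_units = units_a, response = resp_a),
    data.frame(kind = "staircase", staircase_id = "B",
               duration_units = units_b, response = resp_b),
    data.frame(kind = rep(c("positive_control", "negative_control"), each = 2),
               staircase_id = NA, duration_units = NA,
               response = c("yes", "no", "no", "yes"))
  )
  if (!is.null(catch_at)) {
    ord <- order(c(seq_len(na + nb),
                   catch_at - 0.5))
    df <- df[ord, ]
  }
  df$index <- seq_len(nrow(df))
  df$duration_ms <- df$duration_units * 1000 / 75
  df$duration_ms[is.na(df$duration_ms)] <- 0
  class(df) <- c("staircase_session", "data.frame")
  df
}

test_that("flat and alternating runs are at threshold, split by response", {
  u <- c(10, 10, 10, 10, 10, 10)
  r <- c("yes", "no", "yes", "no", "yes", "no")
  s <- make_manual_session(u, r, u, r)
  cs <- classify_trials(s, mode = "sliding")
  stair <- cs$kind == "staircase"
  expect_true(all(cs$category[stair & cs$response == "yes"] == "ST"))
  expect_true(all(cs$category[stair & cs$response == "no"] == "UT"))
})

test_that("the strictly descending opening run is never at threshold", {
  u <- c(30, 25, 20, 15, 10, 5)
  r <- c(rep("yes", 5), "no")
  s <- make_manual_session(u, r)
  cs <- classify_trials(s)
  stair <- cs$kind == "staircase"
  expect_true(all(cs$category[stair] %in% c("SNT", "UNT")))
  expect_equal(cs$category[stair & cs$response == "yes"], rep("SNT", 10))
})

test_that("classification equals the brute-force window labeler", {
  # handcrafted 24-trial staircases plus generated sessions
  set.seed(11)
  ua <- c(30, 25, 20, 15, 10, 5, pmax(1, 5 + cumsum(sample(c(-1, 1), 18, TRUE))))
  ra <- c(rep("yes", 5), sample(c("yes", "no"), 19, TRUE))
  s <- make_manual_session(ua, ra)
  cs <- classify_trials(s)
  at <- brute_force_at_threshold(s)
  expect_equal(cs$category, brute_force_categories(s, at))

  for (seed in c(2, 21, 57)) {
    g <- generate_session(observer(35, 6), seed = seed)
    cg <- classify_trials(g)
    expect_equal(cg$category,
                 brute_force_categories(g, brute_force_at_threshold(g)))
  }
})

test_that("every trial gets exactly one category and counts are conserved", {
  for (seed in c(5, 50)) {
    cs <- classify_trials(generate_session(observer(45, 8), seed = seed))
    expect_false(any(is.na(cs$category)))
    expect_equal(sum(attr(cs, "counts")), 60L)
    # all negative controls are OT
    expect_true(all(cs$category[cs$kind == "negative_control"] == "OT"))
    # ST/UT only on staircase trials
    expect_true(all(cs$kind[cs$category %in% c("ST", "UT")] == "staircase"))
  }
})

test_that("classification ignores catch-trial positions", {
  u <- c(10, 9, 10, 9, 10, 11, 10, 9)
  r <- c("no", "yes", "no", "yes", "no", "yes", "no", "yes")
  s1 <- make_manual_session(u, r, catch_at = NULL)
  s2 <- make_manual_session(u, r, catch_at = c(2, 5, 9, 12))
  c1 <- classify_trials(s1); c2 <- classify_trials(s2)
  k1 <- c1$category[c1$kind == "staircase"]
  k2 <- c2$category[c2$kind == "staircase"]
  expect_equal(k1, k2)
})

test_that("disjoint windows are a strict subset of sliding windows", {
  for (seed in c(9, 14)) {
    s <- generate_session(observer(35, 6), seed = seed)
    sl <- attr(classify_trials(s, mode = "sliding"), "at_threshold")
    dj <- attr(classify_trials(s, mode = "disjoint"), "at_threshold")
    expect_true(all(sl[dj]))
  }
})

test_that("threshold is the mean duration over ST and UT trials", {
  u <- c(3, 3, 3, 3, 3, 3)   # 3 units = 40 ms at 75 Hz
  r <- c("yes", "no", "yes", "no", "yes", "no")
  s <- make_manual_session(u, r, u, r)
  cs <- classify_trials(s)
  expect_equal(estimate_threshold(cs), 40, tolerance = 1e-9)

  # ST = {40, 40}, UT = {53.3, 53.3} -> 46.65 (hand-computed mean)
  mixed <- cs
  at <- which(mixed$category %in% c("ST", "UT"))
  mixed <- mixed[at[1:4], ]
  mixed$category <- c("ST", "ST", "UT", "UT")
  mixed$duration_ms <- c(40, 40, 53.3, 53.3)
  expect_equal(estimate_threshold(mixed), mean(c(40, 40, 53.3, 53.3)))
  expect_equal(estimate_threshold(mixed), 46.65)
})

test_that("a session without at-threshold trials fails loudly, not with 0", {
  u <- c(30, 25, 20, 15, 10, 5)
  r <- c(rep("yes", 5), "no")
  cs <- classify_trials(make_manual_session(u, r))
  expect_warning(thr <- estimate_threshold(cs), "undefined")
  expect_true(is.na(thr))
  expect_error(estimate_threshold(generate_session(observer(35, 6), seed = 1)),
               "classify")
})

test_that("too-short staircases are a classification error", {
  s <- make_manual_session(c(10, 10, 10), c("yes", "no", "yes"))
  expect_error(classify_trials(s), "at least 5")
})
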