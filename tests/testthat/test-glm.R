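test_that("design matrix columns are HRF-convolved onset trains", {
  # no events: only the constant column is non-zero, all conditions flagged
  X0 <- build_design(numeric(0), character(0), tr_s = 3, n_volumes = 20)
  expect_equal(sort(attr(X0, "empty")), sort(c("ST", "UT", "SNT", "UNT", "OT")))
  expect_true(all(X0[, 1:5] == 0))
  expect_true(all(X0[, "constant"] == 1))

  # single ST event: the column equals HRF samples shifted to the onset
  # (direct convolution oracle at the microtime grid)
  onset <- 12.3; dt <- 0.1
  X <- build_design(onset, "ST", tr_s = 3, n_volumes = 30, dt = dt)
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  fine <- numeric(ceiling(90 / dt) + 1)
  fine[floor(onset / dt) + 1 + seq_along(h) - 1] <- h
  expected <- fine[round((0:29) * 3 / dt) + 1]
  expect_equal(unname(X[, "ST"]), expected, tolerance = 1e-12)

  # a full classified session occupies all five conditions
  cs <- classify_trials(generate_session(observer(35, 6), seed = 2))
  Xs <- build_design(cs$onset_s, cs$category, tr_s = 3,
                     n_volumes = ceiling(max(cs$onset_s) / 3) + 10)
  expect_equal(ncol(Xs), 6L)
  expect_length(attr(Xs, "empty"), 0L)

  expect_error(build_design(1000, "ST", 3, 30), "beyond")
})

test_that("OLS recovers noiseless planted amplitudes to machine precision", {
  geom <- bold_geometry(dim = c(6, 6, 4), n_volumes = 60)
  tl <- data.frame(onset_s = seq(5, 173, by = 12),
                   category = rep(c("ST", "UT", "SNT"), 5))
  region <- as.matrix(expand.grid(2:3, 2:3, 2))
  ser <- simulate_bold(tl, list(effect_spec(region, "ST", 2.0),
                                effect_spec(region, "UT", -1.25)),
                       geom, noise = list(white_sd = 0), baseline = 100)
  X <- build_design(tl$onset_s, tl$category, 3, 60)
  fit <- fit_glm(ser, X)
  expect_equal(fit$beta$ST[2, 2, 2], 2.0, tolerance = 1e-9)
  expect_equal(fit$beta$UT[3, 3, 2], -1.25, tolerance = 1e-9)
  expect_equal(fit$beta$constant[2, 2, 2], 100, tolerance = 1e-9)
  off <- fit$beta$ST; off[2:3, 2:3, 2] <- 0
  expect_lt(max(abs(off)), 1e-9)
  expect_equal(fit$df_resid, 60L - 4L)   # ST, UT, SNT, constant retained
})

test_that("voxelwise OLS equals the normal-equations oracle on a tiny fixture", {
  set.seed(12)
  nt <- 20
  tl <- data.frame(onset_s = c(5, 20, 35, 50), category = c("ST", "UT", "ST", "UT"))
  geom <- bold_geometry(dim = c(3, 1, 1), n_volumes = nt)
  ser <- simulate_bold(tl, list(), geom, noise = list(white_sd = 1), seed = 4)
  X <- build_design(tl$onset_s, tl$category, 3, nt)
  fit <- fit_glm(ser, X)
  keep <- c("ST", "UT", "constant")
  Xk <- X[, keep]
  for (v in 1:3) {
    y <- ser$data[v, 1, 1, ]
    beta_ne <- solve(t(Xk) %*% Xk, t(Xk) %*% y)   # independent normal equations
    for (j in seq_along(keep)) {
      expect_equal(fit$beta[[keep[j]]][v, 1, 1], beta_ne[j],
                   tolerance = 1e-10)
    }
  }
})

test_that("rank-deficient designs fail naming the collinear columns", {
  nt <- 20
  tl <- data.frame(onset_s = c(5, 20), category = c("ST", "ST"))
  X <- build_design(tl$onset_s, tl$category, 3, nt)
  X[, "UT"] <- X[, "ST"]          # force collinearity
  attr(X, "empty") <- c("SNT", "UNT", "OT")
  geom <- bold_geometry(dim = c(2, 2, 1), n_volumes = nt)
  ser <- simulate_bold(tl, list(), geom, noise = list(white_sd = 1), seed = 1)
  expect_error(fit_glm(ser, X), "collinear")
})

test_that("random-effects t map has n-1 df and flags zero-variance voxels", {
  d <- c(4, 4, 2)
  mk <- function(x) {
    fake_beta_maps(list(ST = array(x, d), UT = array(0, d)))
  }
  subs <- lapply(c(1.2, 1.2, 1.2), mk)       # identical subjects
  m <- rfx_contrast(subs, c(ST = 1, UT = -1))
  expect_equal(m$df, 2L)
  expect_true(all(is.infinite(m$values)))
  expect_true(all(m$values > 0))

  subs0 <- lapply(c(0, 0, 0), mk)
  expect_true(all(rfx_contrast(subs0, c(ST = 1))$values == 0))
  expect_error(rfx_contrast(subs[1], c(ST = 1)), ">= 2")

  set.seed(31)
  subs19 <- lapply(1:19, function(i) mk(rnorm(prod(d))))
  expect_equal(rfx_contrast(subs19, c(ST = 1))$df, 18L)
})

test_that("contrast maps ignore a per-subject constant shift of all conditions", {
  d <- c(3, 3, 2)
  set.seed(8)
  base <- lapply(1:5, function(i)
    list(ST = array(rnorm(prod(d)), d), UT = array(rnorm(prod(d)), d)))
  subs <- lapply(base, fake_beta_maps)
  shifted <- lapply(seq_along(base), function(i) {
    b <- base[[i]]
    b$ST <- b$ST + i; b$UT <- b$UT + i    # same shift on every condition
    fake_beta_maps(b)
  })
  m1 <- rfx_contrast(subs, c(ST = 1, UT = -1))
  m2 <- rfx_contrast(shifted, c(ST = 1, UT = -1))
  expect_equal(m1$values, m2$values, tolerance = 1e-10)
})

test_that("mixed ANOVA reports the reference degrees of freedom layout", {
  d <- c(2, 2, 1)
  set.seed(17)
  subs <- lapply(1:34, function(i) {
    b <- setNames(lapply(1:5, function(k) array(rnorm(prod(d)), d)),
                  c("ST", "UT", "SNT", "UNT", "OT"))
    fake_beta_maps(b)
  })
  groups <- rep(c("HC", "SCZ"), c(19, 15))
  res <- mixed_anova(subs, groups)
  expect_equal(res$F_between$df, c(1L, 32L))
  expect_equal(res$F_within$df, c(4L, 128L))
  expect_equal(res$F_interaction$df, c(4L, 128L))

  # all-equal betas give F = 0 everywhere
  flat <- lapply(1:6, function(i) {
    b <- setNames(lapply(1:5, function(k) array(3, d)), c("ST", "UT", "SNT", "UNT", "OT"))
    fake_beta_maps(b)
  })
  r0 <- mixed_anova(flat, rep(c("HC", "SCZ"), each = 3))
  expect_true(all(r0$F_between$values == 0))
  expect_true(all(r0$F_within$values == 0))
})

test_that("mixed ANOVA matches the aov() sums-of-squares oracle", {
  conds <- c("ST", "UT", "SNT")
  set.seed(99)
  for (rep_k in 1:3) {
    n <- 8
    groups <- rep(c("HC", "SCZ"), each = 4)
    vals <- lapply(1:n, function(i)
      setNames(lapply(conds, function(cc) array(rnorm(2), c(2, 1, 1))), conds))
    subs <- lapply(vals, fake_beta_maps)
    res <- mixed_anova(subs, groups, conditions = conds)
    for (v in 1:2) {
      y <- unlist(lapply(1:n, function(i)
        sapply(conds, function(cc) vals[[i]][[cc]][v, 1, 1])))
      df <- data.frame(y = y,
                       subj = factor(rep(1:n, each = 3)),
                       cond = factor(rep(conds, n)),
                       group = factor(rep(groups, each = 3)))
      a <- summary(stats::aov(y ~ group * cond + Error(subj), data = df))
      tab_b <- a[["Error: subj"]][[1]]
      tab_w <- a[["Error: Within"]][[1]]
      f_group <- tab_b[trimws(rownames(tab_b)) == "group", "F value"]
      f_cond <- tab_w[trimws(rownames(tab_w)) == "cond", "F value"]
      f_int <- tab_w[trimws(rownames(tab_w)) == "group:cond", "F value"]
      expect_equal(res$F_between$values[v, 1, 1], f_group, tolerance = 1e-8)
      expect_equal(res$F_within$values[v, 1, 1], f_cond, tolerance = 1e-8)
      expect_equal(res$F_interaction$values[v, 1, 1], f_int, tolerance = 1e-8)
    }
  }
})

test_that("post-hoc group maps: df modes, antisymmetry, planted deficits", {
  d <- c(5, 5, 3)
  set.seed(23)
  region <- array(FALSE, d); region[2:3, 2:3, 2] <- TRUE
  mk <- function(group) {
    st <- array(rnorm(prod(d), 0, 0.1), d)
    ut <- array(rnorm(prod(d), 0, 0.1), d)
    if (group == "SCZ") ut[region] <- ut[region] - 3   # planted UT deficit
    fake_beta_maps(list(ST = st, UT = ut))
  }
  groups <- rep(c("HC", "SCZ"), each = 8)
  subs <- lapply(groups, mk)

  m <- posthoc_group_map(subs, groups, weights = c(UT = 1),
                         df_mode = "anova_pooled", n_conditions = 5)
  expect_equal(m$df, (16 - 1) * (5 - 1))
  m2 <- posthoc_group_map(subs, groups, weights = c(UT = 1),
                          df_mode = "two_sample")
  expect_equal(m2$df, 14L)
  expect_equal(m$values, m2$values)     # statistic identical, df differs

  # the planted deficit region is strongly positive (HC - SCZ), the rest is not
  crit <- critical_t(0.01, m2$df)
  expect_true(all(m$values[region] > crit))
  expect_lt(mean(abs(m$values[!region]) > crit), 0.1)

  # permuting group labels flips the sign
  flipped <- posthoc_group_map(subs, factor(groups, levels = c("SCZ", "HC")),
                               weights = c(UT = 1))
  expect_equal(flipped$values, -m$values, tolerance = 1e-10)
})

test_that("second-level covariates are accepted and reduce the df", {
  d <- c(3, 3, 2)
  set.seed(41)
  subs <- lapply(1:10, function(i)
    fake_beta_maps(list(ST = array(rnorm(prod(d), 1), d))))
  covs <- cbind(med = rnorm(10), panss = rnorm(10))
  m <- rfx_contrast(subs, c(ST = 1), covariates = covs)
  expect_equal(m$df, 10L - 3L)
  expect_length(m$covariate_maps, 2L)
})

test_that("map thresholds reproduce the printed critical values", {
  expect_equal(critical_t(0.01, 132), 2.61, tolerance = 0.005)
  expect_equal(critical_t(0.01, 32), 2.74, tolerance = 0.005)
})
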