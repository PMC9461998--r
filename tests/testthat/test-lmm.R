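test_that("model frame encodes contrasts, scaling and orthogonal polynomials", {
  set.seed(4)
  d <- data.frame(canonicity = rep(c("C", "N"), 50),
                  prestim = rnorm(100), surprisal = runif(100, 0, 3))
  mf <- build_model_frame(d, sum_code = "canonicity",
                          zscore = c("prestim", "surprisal"),
                          poly = list(surprisal = 3))
  expect_setequal(unique(mf$canonicity), c(1, -1))
  expect_equal(mean(mf$canonicity), 0)           # balanced
  expect_equal(mean(mf$prestim), 0, tolerance = 1e-12)
  expect_equal(stats::sd(mf$prestim), 1, tolerance = 1e-12)
  # orthogonal polynomial columns: Gram matrix is diagonal
  P <- as.matrix(mf[, c("surprisal_p1", "surprisal_p2", "surprisal_p3")])
  G <- crossprod(P)
  expect_equal(G, diag(diag(G)), tolerance = 1e-10, ignore_attr = TRUE)

  # transforms re-apply to new data with the stored constants
  d2 <- data.frame(canonicity = c("N", "C"), prestim = c(10, -10),
                   surprisal = c(1, 2))
  mf2 <- build_model_frame(d2, sum_code = "canonicity",
                           zscore = c("prestim", "surprisal"),
                           poly = list(surprisal = 3),
                           transforms = attr(mf, "transforms"))
  tr <- attr(mf, "transforms")
  expect_equal(mf2$prestim[1],
               (10 - tr$zscore$prestim[["mean"]]) / tr$zscore$prestim[["sd"]])
  expect_equal(mf2$canonicity, c(-1, 1))

  expect_error(build_model_frame(d, zscore = "nope"), "unknown column")
  d$flat <- 1
  expect_error(build_model_frame(d, zscore = "flat"), "constant")
  d$prestim[3] <- NA
  expect_message(build_model_frame(d, zscore = "prestim"), "dropped")
})

test_that("balanced one-way variance components match closed-form REML", {
  set.seed(15)
  G <- 12; n_per <- 8
  g <- rep(sprintf("g%02d", seq_len(G)), each = n_per)
  b <- rnorm(G, 0, 2)
  y <- 5 + b[as.integer(factor(g))] + rnorm(G * n_per, 0, 1)
  d <- data.frame(y = y, g = g)
  fit <- fit_vc_lmm(y ~ 1 + (1 | g), d, REML = TRUE)

  # closed-form ANOVA estimators (equal REML on balanced one-way layouts)
  gm <- tapply(y, g, mean)
  msb <- n_per * sum((gm - mean(y))^2) / (G - 1)
  msw <- sum((y - gm[g])^2) / (G * (n_per - 1))
  sigma_b2 <- max((msb - msw) / n_per, 0)
  expect_equal(unname(fit$sd_components[1]^2), sigma_b2, tolerance = 1e-6)
  expect_equal(fit$sigma^2, msw, tolerance = 1e-6)
  expect_equal(fit$beta$estimate[1], mean(y), tolerance = 1e-8)

  # group means forced exactly equal: the component sits on the boundary
  y0 <- rnorm(G * n_per)
  y0 <- y0 - stats::ave(y0, g) + mean(y0)
  fit0 <- fit_vc_lmm(y ~ 1 + (1 | g), data.frame(y = y0, g = g), REML = TRUE)
  expect_lt(fit0$sd_components[1], 1e-4)
})

test_that("ML deviance agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(25)
  d <- expand.grid(g = sprintf("g%02d", 1:25), h = sprintf("h%02d", 1:6))
  d$x <- rnorm(nrow(d)); d$w <- rnorm(nrow(d))
  d$y <- 1 + 2 * d$x - d$w +
    rnorm(25, 0, 1.5)[as.integer(d$g)] + rnorm(6, 0, 0.8)[as.integer(d$h)] +
    rnorm(nrow(d))
  f <- y ~ x + w + (1 | g) + (1 | h)
  for (reml in c(FALSE, TRUE)) {
    fit <- fit_vc_lmm(f, d, REML = reml)
    ref <- lme4::lmer(f, d, REML = reml)
    ref_dev <- if (reml) lme4::REMLcrit(ref) else deviance(ref)
    expect_lt(abs(fit$deviance - ref_dev), 1e-3)
    expect_equal(fit$beta$estimate, unname(lme4::fixef(ref)),
                 tolerance = 1e-5)
    expect_equal(fit$sigma, sigma(ref), tolerance = 1e-4)
  }
  # a variance-components slope term matches lme4's double-bar coding
  d$z <- rnorm(nrow(d))
  fit2 <- fit_vc_lmm(y ~ x + (1 | g) + (0 + z | g), d, REML = FALSE)
  ref2 <- lme4::lmer(y ~ x + (1 | g) + (0 + z | g), d, REML = FALSE)
  expect_lt(abs(fit2$deviance - deviance(ref2)), 1e-3)
})

test_that("zero variance components reduce fixed effects to ordinary least squares", {
  set.seed(35)
  d <- data.frame(g = rep(sprintf("g%02d", 1:10), each = 10), x = rnorm(100))
  d$y <- 2 + 3 * d$x + rnorm(100)          # no grouping structure
  fit <- fit_vc_lmm(y ~ x + (1 | g), d, REML = FALSE)
  ols <- stats::lm(y ~ x, d)
  if (max(fit$theta) < 1e-4) {
    expect_equal(fit$beta$estimate, unname(coef(ols)), tolerance = 1e-6)
  } else {
    # small estimated component: coefficients still close to OLS
    expect_equal(fit$beta$estimate, unname(coef(ols)), tolerance = 1e-2)
  }
  expect_error(fit_vc_lmm(y ~ x, d), "random-effect term")
  d$x2 <- d$x
  expect_error(fit_vc_lmm(y ~ x + x2 + (1 | g), d), "singular")
})

test_that("model comparison reports criteria and likelihood-ratio tests", {
  set.seed(45)
  d <- data.frame(g = rep(sprintf("g%02d", 1:15), each = 6), x = rnorm(90))
  d$y <- 1 + 0.5 * d$x + rnorm(15, 0, 1)[as.integer(factor(d$g))] + rnorm(90)
  m0 <- fit_vc_lmm(y ~ 1 + (1 | g), d, REML = FALSE)
  m1 <- fit_vc_lmm(y ~ x + (1 | g), d, REML = FALSE)
  tab <- compare_models(list(null = m0, slope = m1))
  expect_equal(tab$Model, c("null", "slope"))
  expect_true(all(tab$AICc > tab$AIC))
  expect_equal(tab$lrt_stat[2], m0$deviance - m1$deviance)
  expect_equal(tab$lrt_df[2], 1L)
  # identical model twice: statistic 0, df 0
  tab0 <- compare_models(list(a = m0, b = m0))
  expect_equal(tab0$lrt_stat[2], 0)
  expect_equal(tab0$lrt_df[2], 0L)
  # ML deviance non-increasing when adding a fixed effect
  expect_lte(m1$deviance, m0$deviance)
  expect_error(compare_models(list(fit_vc_lmm(y ~ 1 + (1 | g), d, REML = TRUE),
                                   m1)), "require ML")
})

test_that("the LRT statistic for a spurious predictor is chi-square(1)", {
  set.seed(55)
  n_rep <- 60
  stats_lrt <- numeric(n_rep)
  g <- rep(sprintf("g%02d", 1:10), each = 6)
  for (r in seq_len(n_rep)) {
    d <- data.frame(g = g, x = rnorm(60),
                    y = rnorm(10, 0, 1)[as.integer(factor(g))] + rnorm(60))
    m0 <- fit_vc_lmm(y ~ 1 + (1 | g), d, REML = FALSE)
    m1 <- fit_vc_lmm(y ~ x + (1 | g), d, REML = FALSE)
    stats_lrt[r] <- max(m0$deviance - m1$deviance, 0)
  }
  ks <- stats::ks.test(stats_lrt, stats::pchisq, df = 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("partial effects remove exactly the requested contributions", {
  set.seed(65)
  nps <- make_scaled_session(n_passages = 20, seed = 6)
  parts <- gen_participants(12, seed = 3)
  cfg <- sim_config(seed = 2, n_subjects = 12, n_items = 40, n_channels = 1)
  tr <- simulate_trial_amplitudes(nps, parts, cfg)
  tr <- build_model_frame(tr, sum_code = "canonicity")
  fit <- fit_vc_lmm(
    amplitude ~ surprisal * epoch_z + canonicity + prestim +
      (1 | subject) + (1 | item), tr, REML = TRUE)

  # keep everything: the observed response, bit for bit
  expect_identical(partial_effects(fit), fit$y)

  # keep nothing: residual regression on removed predictors has slope ~ 0
  adj <- partial_effects(fit, keep_fixed = character(0),
                         keep_re = character(0))
  for (v in c("surprisal", "prestim")) {
    sl <- coef(stats::lm(adj ~ tr[[v]]))[2]
    expect_lt(abs(sl), 0.02)
  }

  # removing only canonicity closes the group gap by exactly 2|beta|
  adj_c <- partial_effects(fit,
                           keep_fixed = setdiff(
                             attr(fit$terms, "term.labels"), "canonicity"))
  b_can <- fit$beta$estimate[fit$beta$term == "canonicity"]
  gap_before <- mean(fit$y[tr$canonicity == 1]) -
    mean(fit$y[tr$canonicity == -1])
  gap_after <- mean(adj_c[tr$canonicity == 1]) -
    mean(adj_c[tr$canonicity == -1])
  expect_equal(gap_before - gap_after, 2 * b_can, tolerance = 1e-10)

  expect_error(partial_effects(fit, keep_fixed = "nope"), "unknown fixed")
  expect_error(partial_effects(fit, keep_re = "nope"), "unknown random")

  # rePCA-style report: proportions sum to one per grouping factor
  rp <- re_pca(fit)
  expect_setequal(names(rp), c("subject", "item"))
  expect_equal(sum(rp$subject$prop_var), 1)
})

test_that("recovery studies are reproducible and recover planted moderation", {
  nps <- make_scaled_session(n_passages = 15, seed = 9)
  parts <- gen_participants(10, seed = 8)
  cfg <- sim_config(seed = 1, n_subjects = 10, n_items = 30, n_channels = 1,
                    resid_sd = 2)
  f <- amplitude ~ surprisal * epoch_z + canonicity + (1 | subject) + (1 | item)
  r1 <- recovery_study(nps, parts, cfg, f,
                       truth = c("surprisal:epoch_z" = -0.5),
                       n_reps = 3, seed = 77)
  r2 <- recovery_study(nps, parts, cfg, f,
                       truth = c("surprisal:epoch_z" = -0.5),
                       n_reps = 3, seed = 77)
  expect_identical(attr(r1, "estimates"), attr(r2, "estimates"))
  expect_true(all(r1$coverage >= 0 & r1$coverage <= 1))

  # planted covariate moderation: correct (negative) sign in >= 95% of reps
  cfg_m <- sim_config(seed = 1, n_subjects = 24, n_items = 30, n_channels = 1,
                      beta_true = c(intercept = 1, surprisal = -1.5,
                                    epoch = 0.5, surprisal_epoch = -0.5,
                                    canonicity = 0.5,
                                    slope_surprisal_epoch = -0.8),
                      resid_sd = 2)
  parts_m <- gen_participants(24, seed = 4)
  f_m <- amplitude ~ surprisal * epoch_z * slope_z + canonicity +
    (1 | subject) + (1 | item)
  est <- numeric(20)
  for (r in seq_len(20)) {
    cfg_r <- cfg_m; cfg_r$seed <- 1000L + r
    tr <- simulate_trial_amplitudes(nps, parts_m, cfg_r)
    tr$slope_z <- as.numeric(scale(tr$slope))
    fit <- fit_vc_lmm(f_m, tr, REML = FALSE)
    est[r] <- fit$beta$estimate[fit$beta$term == "surprisal:epoch_z:slope_z"]
  }
  expect_gte(mean(est < 0), 0.95)
})
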