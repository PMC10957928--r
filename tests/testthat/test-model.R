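sim_xy <- function(n = 80, p = 6, seed = 412) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  eta <- X[, 1] * 1.5 - X[, 2] + stats::rnorm(n, sd = 0.5)
  y <- as.numeric(stats::runif(n) < stats::plogis(eta))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y)
}

test_that("above lambda_max the fit collapses to the intercept-only model", {
  d <- sim_xy()
  lmax <- lambda_max(d$X, d$y)
  fit <- fit_l1_logistic(d$X, d$y, lmax * 1.001)
  expect_true(all(fit$beta == 0))
  prev <- mean(d$y)
  expect_equal(fit$intercept, stats::qlogis(prev), tolerance = 1e-6)
  expect_equal(unname(predict(fit, d$X)), rep(prev, nrow(d$X)), tolerance = 1e-8)
  # and just below lambda_max something activates
  fit2 <- fit_l1_logistic(d$X, d$y, lmax * 0.9)
  expect_gt(sum(fit2$beta != 0), 0)
})

test_that("the unpenalized limit matches an independent maximum-likelihood fit", {
  # a small non-separable instance, so the unpenalized MLE exists
  X <- matrix(
    c(
      0.22, -0.54, 0.89, 0.60, 1.64, 0.69, -1.28, -0.21,
      1.90, 1.78, 0.57, 0.02, 0.38, -0.05, 0.03, 0.17
    ),
    nrow = 8, dimnames = list(NULL, c("x1", "x2"))
  )
  y <- c(0, 1, 1, 0, 1, 1, 0, 0)
  ours <- suppressWarnings(fit_l1_logistic(X, y, lambda = 0, thresh = 1e-14))
  ref <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(ours$intercept, unname(stats::coef(ref)[1]), tolerance = 1e-5)
  expect_equal(unname(ours$beta), unname(stats::coef(ref)[-1]), tolerance = 1e-5)
})

test_that("KKT subgradient conditions hold at every fitted lambda", {
  d <- sim_xy(n = 120, p = 10, seed = 413)
  lmax <- lambda_max(d$X, d$y)
  grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 12))
  for (lam in grid) {
    fit <- fit_l1_logistic(d$X, d$y, lam, thresh = 1e-12)
    kkt <- kkt_residuals(fit, d$X, d$y)
    expect_lt(kkt$max_violation_zero, 1e-5)
    expect_lt(kkt$max_violation_active, 1e-5)
  }
})

test_that("the L1 norm of coefficients grows as the penalty shrinks", {
  d <- sim_xy(n = 150, p = 8, seed = 414)
  lmax <- lambda_max(d$X, d$y)
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 25))
  norms <- vapply(grid, function(lam) {
    sum(abs(fit_l1_logistic(d$X, d$y, lam)$beta))
  }, numeric(1))
  expect_true(all(diff(norms) >= -1e-6)) # grid is decreasing in lambda
})

test_that("fit errors on degenerate inputs", {
  d <- sim_xy()
  expect_error(fit_l1_logistic(d$X, rep(1, nrow(d$X)), 0.1), class = "ecre_input_error")
  Xbad <- d$X
  Xbad[1, 1] <- NA
  expect_error(fit_l1_logistic(Xbad, d$y, 0.1), class = "ecre_input_error")
})

test_that("cross-validation picks a penalty that keeps a separating feature", {
  set.seed(415)
  n <- 100
  X <- cbind(
    signal = rep(c(0, 1), each = n / 2),
    noise1 = stats::rnorm(n), noise2 = stats::rnorm(n)
  )
  y <- rep(c(0, 1), each = n / 2)
  cv <- cv_select_lambda(X, y, k = 5)
  fit <- fit_l1_logistic(X, y, cv$lambda_min)
  expect_gt(abs(fit$beta["signal"]), 0)

  set.seed(416)
  one <- cv_select_lambda(X, y, k = 5, lambda = 0.03)
  expect_equal(one$lambda_min, 0.03)

  set.seed(417)
  a <- cv_select_lambda(X, y, k = 5)
  set.seed(417)
  b <- cv_select_lambda(X, y, k = 5)
  expect_identical(a, b)
  expect_error(cv_select_lambda(X, y, k = 200), class = "ecre_input_error")
})

test_that("enhancer calls use a strict threshold", {
  # the six published table scores give exactly four calls at 0.5
  scores <- c(0.7015349, 0.6563047, 0.6256454, 0.5127832, 0.4803304, 0.3063491)
  expect_equal(sum(classify(scores, 0.5)), 4)
  expect_true(classify(0.6563047))
  expect_false(classify(0.4803304))
  expect_false(classify(0.5)) # exactly at threshold is not a call
  expect_error(classify(1.2), class = "ecre_input_error")
  expect_error(classify(-0.1), class = "ecre_input_error")
})

separable_library <- function(genome, enh) {
  cfg <- sim_config(
    seed = 51, n_chrom = 2, chrom_length = 2e6, n_pos = 80,
    n_informative = 3, n_noise = 2, p_fg = 1, p_bg = 0, n_genes = 10
  )
  trk <- simulate_tracks(cfg, genome, enh)
  track_library(trk$tracks)
}

test_that("a perfectly informative library yields perfect test accuracy", {
  cfg <- sim_config(
    seed = 51, n_chrom = 2, chrom_length = 2e6, n_pos = 80,
    n_informative = 3, n_noise = 2, p_fg = 1, p_bg = 0, n_genes = 10
  )
  genome <- make_genome(cfg)
  enh <- simulate_enhancers(cfg, genome)
  lib <- separable_library(genome, enh)
  set.seed(418)
  run <- train_once(enh, lib, genome, config = train_config(cv_folds = 5, nlambda = 40))
  expect_equal(run$accuracy, 1.0)

  set.seed(418)
  rerun <- train_once(enh, lib, genome, config = train_config(cv_folds = 5, nlambda = 40))
  expect_identical(rerun$fit, run$fit)
})

test_that("an uninformative library scores at chance on the test split", {
  cfg <- sim_config(
    seed = 52, n_chrom = 5, chrom_length = 8e6, n_pos = 695,
    n_informative = 0, n_noise = 6, p_fg = 0.05, p_bg = 0.05, n_genes = 10
  )
  genome <- make_genome(cfg)
  enh <- simulate_enhancers(cfg, genome)
  trk <- simulate_tracks(cfg, genome, enh)
  set.seed(419)
  run <- train_once(enh, track_library(trk$tracks), genome,
    config = train_config(cv_folds = 5, nlambda = 40)
  )
  n_test <- 2 * round(0.2 * 695)
  band <- stats::qbinom(c(0.005, 0.995), n_test, 0.5) / n_test
  expect_gte(run$accuracy, band[1])
  expect_lte(run$accuracy, band[2])
})

test_that("the ensemble averages per-repeat scores and is seed-stable", {
  cfg <- sim_config(
    seed = 53, n_chrom = 2, chrom_length = 2e6, n_pos = 60,
    n_informative = 3, n_noise = 2, p_fg = 0.95, p_bg = 0.02, n_genes = 10
  )
  genome <- make_genome(cfg)
  enh <- simulate_enhancers(cfg, genome)
  trk <- simulate_tracks(cfg, genome, enh)
  lib <- track_library(trk$tracks)
  queries <- enh[1:10, 1:3]
  tc <- train_config(repeats = 3, seed = 9, cv_folds = 5, nlambda = 30)
  ens <- ensemble_predict(enh[11:60, ], lib, genome, queries = queries, config = tc)
  reps <- as.matrix(ens$scores[, paste0("score_rep", 1:3)])
  expect_equal(ens$scores$mean_score, rowMeans(reps))
  expect_true(all(ens$scores$mean_score >= apply(reps, 1, min) - 1e-12))
  expect_true(all(ens$scores$mean_score <= apply(reps, 1, max) + 1e-12))
  expect_equal(ens$scores$is_enhancer, ens$scores$mean_score > 0.5)

  ens2 <- ensemble_predict(enh[11:60, ], lib, genome, queries = queries, config = tc)
  expect_identical(ens$scores, ens2$scores)

  one <- ensemble_predict(enh[11:60, ], lib, genome,
    queries = queries,
    config = train_config(repeats = 1, seed = 9, cv_folds = 5, nlambda = 30)
  )
  expect_equal(one$scores$mean_score, one$scores$score_rep1)

  g <- glance(ens)
  expect_equal(g$repeats, 3L)
  expect_equal(g$n_queries, 10L)
})

test_that("model JSON dumps reload to the same predictions", {
  d <- sim_xy()
  fit <- fit_l1_logistic(d$X, d$y, 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_lasso_fit(fit, path)
  back <- read_lasso_fit(path)
  expect_equal(predict(back, d$X), predict(fit, d$X), tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$estimate[1], fit$intercept)
})
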