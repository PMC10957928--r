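#' Training configuration for the ensemble enhancer classifier
#'
#' Defaults follow the published workflow: an 80/20 stratified train/test
#' split, 10-fold cross-validation over a 100-value geometric lambda grid
#' spanning four decades below the data-driven `lambda_max`, 10 ensemble
#' repeats with freshly resampled negatives, and a 0.5 decision threshold on
#' the averaged score.
#'
#' @param train_frac Fraction of labeled rows used for training.
#' @param cv_folds Number of cross-validation folds (stratified by label).
#' @param nlambda Length of the lambda grid.
#' @param lambda_min_ratio Smallest grid value as a fraction of `lambda_max`.
#' @param repeats Number of ensemble repeats.
#' @param threshold Decision threshold on the mean score (strict `>`).
#' @param seed Master seed for negatives, splits and folds.
#' @return A `train_config` list.
#' @export
train_config <- function(train_frac = 0.8, cv_folds = 10L, nlambda = 100L,
                         lambda_min_ratio = 1e-4, repeats = 10L,
                         threshold = 0.5, seed = 1L) {
  stopifnot(
    train_frac > 0, train_frac < 1, cv_folds >= 2, repeats >= 1,
    threshold > 0, threshold < 1, nlambda >= 1, lambda_min_ratio > 0
  )
  structure(
    list(
      train_frac = train_frac, cv_folds = as.integer(cv_folds),
      nlambda = as.integer(nlambda), lambda_min_ratio = lambda_min_ratio,
      repeats = as.integer(repeats), threshold = threshold,
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Fit an L1-penalized (lasso) logistic regression at a fixed penalty
#'
#' Minimizes the penalized average negative log-likelihood
#' `(1/n) * sum_i [-y_i log p_i - (1 - y_i) log(1 - p_i)] + lambda * ||beta||_1`
#' with an unpenalized intercept. Features (including binary columns) are
#' standardized to zero mean and unit variance internally; coefficients are
#' reported on the original scale. At `lambda >= lambda_max` all coefficients
#' are exactly zero and the intercept equals `logit(mean(y))`.
#'
#' @param X Numeric feature matrix (finite values).
#' @param y 0/1 labels; both classes must be present.
#' @param lambda Non-negative penalty strength.
#' @param thresh Optimizer convergence threshold (passed to glmnet).
#' @return A `lasso_fit`: intercept, named coefficient vector, `lambda`, the
#'   standardization parameters and training size.
#' @export
fit_l1_logistic <- function(X, y, lambda, thresh = 1e-10) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) {
    rlang::abort("non-finite values in feature matrix", class = "ecre_input_error")
  }
  if (length(unique(y)) < 2) {
    rlang::abort("both classes must be present in y", class = "ecre_input_error")
  }
  stopifnot(lambda >= 0, nrow(X) >= 2, nrow(X) == length(y))
  fit <- glmnet::glmnet(X, y,
    family = "binomial", alpha = 1, lambda = lambda,
    standardize = TRUE, thresh = thresh, maxit = 1e6
  )
  cf <- as.numeric(stats::coef(fit))
  center <- colMeans(X)
  scale_ <- sqrt(colMeans(sweep(X, 2, center)^2)) # glmnet's 1/n convention
  structure(
    list(
      intercept = cf[1],
      beta = stats::setNames(cf[-1], colnames(X)),
      lambda = lambda,
      center = center,
      scale = scale_,
      n_train = nrow(X)
    ),
    class = "lasso_fit"
  )
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(
    "<lasso_fit> lambda =", signif(x$lambda, 4), "|",
    sum(x$beta != 0), "of", length(x$beta), "nonzero coefficients\n"
  )
  invisible(x)
}

#' Predicted enhancer probabilities from a lasso fit
#'
#' @param object A `lasso_fit`.
#' @param newdata Numeric matrix or `feature_matrix` with the same columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else as.matrix(newdata)
  eta <- drop(object$intercept + X[, names(object$beta), drop = FALSE] %*% object$beta)
  stats::plogis(eta)
}

#' @exportS3Method generics::tidy
tidy.lasso_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$beta)),
    estimate = c(x$intercept, unname(x$beta))
  )
}

#' @exportS3Method generics::glance
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    n_nonzero = sum(x$beta != 0),
    n_features = length(x$beta),
    n_train = x$n_train
  )
}

#' Smallest penalty that zeroes every coefficient
#'
#' For the standardized binomial lasso this is
#' `max_j |<x_std_j, y - mean(y)>| / n`.
#'
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @return A single non-negative number.
#' @export
lambda_max <- function(X, y) {
  X <- as.matrix(X)
  center <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, center)^2))
  s[s == 0] <- 1
  xs <- sweep(sweep(X, 2, center), 2, s, "/")
  r <- y - mean(y)
  max(abs(crossprod(xs, r))) / nrow(X)
}

#' Karush-Kuhn-Tucker optimality residuals of a lasso fit
#'
#' In the standardized coordinates the fitted solution must satisfy
#' `|g_j| <= lambda` for every zeroed coefficient and `g_j = -lambda *
#' sign(beta_j)` for active ones, where `g_j` is the gradient of the average
#' negative log-likelihood. Returns the worst violation of each condition.
#'
#' @param fit A `lasso_fit`.
#' @param X,y The training data the fit was produced from.
#' @return A list with `max_violation_zero` and `max_violation_active`.
#' @export
kkt_residuals <- function(fit, X, y) {
  X <- as.matrix(X)
  keep <- fit$scale > 0
  xs <- sweep(sweep(X[, keep, drop = FALSE], 2, fit$center[keep]), 2, fit$scale[keep], "/")
  p <- predict(fit, X)
  g <- drop(crossprod(xs, p - y)) / nrow(X)
  b_std <- fit$beta[keep] * fit$scale[keep]
  zero <- b_std == 0
  list(
    max_violation_zero = if (any(zero)) max(pmax(abs(g[zero]) - fit$lambda, 0)) else 0,
    max_violation_active = if (any(!zero)) max(abs(g[!zero] + fit$lambda * sign(b_std[!zero]))) else 0
  )
}

stratified_folds <- function(y, k) {
  n <- length(y)
  if (k > n) {
    rlang::abort("more folds than observations", class = "ecre_input_error")
  }
  foldid <- integer(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Choose the lasso penalty by stratified K-fold cross-validation
#'
#' Builds a geometric lambda grid from the data (or uses a supplied grid),
#' assigns label-stratified folds from the current RNG state, and selects the
#' grid value minimizing the mean held-out binomial deviance.
#'
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param k Number of folds.
#' @param nlambda,lambda_min_ratio Grid size and span (used when `lambda` is
#'   `NULL`).
#' @param lambda Optional explicit penalty grid (decreasing); a length-1 grid
#'   is allowed and trivially selected.
#' @return A `cv_lasso`: `lambda` grid, mean CV deviance `cvm`, chosen
#'   `lambda_min`, and the fold assignment.
#' @export
cv_select_lambda <- function(X, y, k = 10L, nlambda = 100L,
                             lambda_min_ratio = 1e-4, lambda = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) {
    rlang::abort("more folds than observations", class = "ecre_input_error")
  }
  if (is.null(lambda)) {
    lmax <- lambda_max(X, y)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  foldid <- stratified_folds(y, k)
  dev <- matrix(NA_real_, k, length(lambda))
  for (f in seq_len(k)) {
    tr <- foldid != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
      family = "binomial", alpha = 1, lambda = lambda, standardize = TRUE
    )
    pr <- stats::predict(fit,
      newx = X[!tr, , drop = FALSE],
      type = "response", s = lambda, exact = FALSE
    )
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    yv <- y[!tr]
    dev[f, ] <- colMeans(-2 * (yv * log(pr) + (1 - yv) * log(1 - pr)))
  }
  cvm <- colMeans(dev)
  structure(
    list(
      lambda = lambda, cvm = cvm,
      lambda_min = lambda[which.min(cvm)], foldid = foldid
    ),
    class = "cv_lasso"
  )
}

#' @export
print.cv_lasso <- function(x, ...) {
  cat(
    "<cv_lasso>", length(x$lambda), "lambda values; lambda_min =",
    signif(x$lambda_min, 4), "\n"
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_lasso <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, mean_deviance = x$cvm)
}

#' @exportS3Method generics::glance
glance.cv_lasso <- function(x, ...) {
  tibble::tibble(
    lambda_min = x$lambda_min,
    n_lambda = length(x$lambda),
    min_deviance = min(x$cvm)
  )
}

#' Strict-threshold enhancer call
#'
#' A region is called an enhancer when its score strictly exceeds the
#' threshold; a score exactly at the threshold is not called.
#'
#' @param score Numeric scores in `[0, 1]`.
#' @param tau Threshold in (0, 1), default 0.5.
#' @return Logical vector.
#' @examples
#' classify(c(0.6563047, 0.4803304, 0.5))
#' @export
classify <- function(score, tau = 0.5) {
  if (any(score < 0 | score > 1, na.rm = TRUE) || anyNA(score)) {
    rlang::abort("scores must lie in [0, 1]", class = "ecre_input_error")
  }
  stopifnot(tau > 0, tau < 1)
  score > tau
}

#' One training repeat: fresh negatives, split, CV, fit, test accuracy
#'
#' Samples matched negatives by genome shuffling (excluding the positives and
#' any blacklist), assembles the labeled feature matrix, draws a stratified
#' train/test split, selects the penalty by cross-validation on the training
#' portion only, fits at the selected penalty, and reports the test accuracy
#' at the configured threshold plus scores for any query regions.
#'
#' @param pos Positive (validated enhancer) regions.
#' @param tracks A [track_library()].
#' @param genome Genome tibble.
#' @param excl Extra exclusion regions for negative sampling (e.g. blacklist).
#' @param queries Optional regions to score with the final fit.
#' @param config A [train_config()].
#' @param query_features Optional precomputed `feature_matrix` for `queries`
#'   (saves recomputation across ensemble repeats).
#' @return A list: `fit` (`lasso_fit`), `cv` (`cv_lasso`), `accuracy`,
#'   `scores` (tibble `region_id`, `score`), `negatives`.
#' @export
train_once <- function(pos, tracks, genome, excl = NULL, queries = NULL,
                       config = train_config(), query_features = NULL) {
  pos <- as_regions(pos)
  shuffle_excl <- dplyr::bind_rows(
    pos[, c("chrom", "start", "end")],
    if (!is.null(excl) && nrow(excl) > 0) as_regions(excl)[, c("chrom", "start", "end")]
  )
  neg <- shuffle_match(pos, genome, excl = shuffle_excl)
  fm <- assemble_features(pos, neg, tracks)

  n <- nrow(fm$X)
  idx_pos <- which(fm$y == 1)
  idx_neg <- which(fm$y == 0)
  tr <- c(
    sample(idx_pos, round(config$train_frac * length(idx_pos))),
    sample(idx_neg, round(config$train_frac * length(idx_neg)))
  )
  te <- setdiff(seq_len(n), tr)

  cv <- cv_select_lambda(fm$X[tr, , drop = FALSE], fm$y[tr],
    k = config$cv_folds, nlambda = config$nlambda,
    lambda_min_ratio = config$lambda_min_ratio
  )
  fit <- fit_l1_logistic(fm$X[tr, , drop = FALSE], fm$y[tr], cv$lambda_min)

  test_scores <- predict(fit, fm$X[te, , drop = FALSE])
  accuracy <- mean(classify(test_scores, config$threshold) == (fm$y[te] == 1))

  scores <- NULL
  if (!is.null(query_features) || !is.null(queries)) {
    qf <- if (!is.null(query_features)) {
      query_features
    } else {
      assemble_features(as_regions(queries), NULL, tracks)
    }
    scores <- tibble::tibble(
      region_id = rownames(qf$X),
      score = unname(predict(fit, qf))
    )
  }
  list(fit = fit, cv = cv, accuracy = accuracy, scores = scores, negatives = neg)
}

#' Ensemble enhancer scoring with repeated negative resampling
#'
#' Runs [train_once()] `config$repeats` times, each repeat with freshly
#' shuffled negatives, a fresh stratified split and fresh CV folds (all
#' derived from substreams of `config$seed`), and averages the per-repeat
#' query scores. A query is called an enhancer when its mean score strictly
#' exceeds the threshold.
#'
#' @inheritParams train_once
#' @return An `ensemble_score`: `scores` tibble (`region_id`, one
#'   `score_rep*` column per repeat, `mean_score`, `is_enhancer`), per-repeat
#'   `accuracies` and `lambdas`, the fitted models, and the config.
#' @export
ensemble_predict <- function(pos, tracks, genome, excl = NULL, queries = NULL,
                             config = train_config()) {
  stopifnot(config$repeats >= 1)
  query_features <- if (!is.null(queries)) {
    assemble_features(as_regions(queries), NULL, tracks)
  } else {
    NULL
  }
  runs <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    set.seed(substream_seed(config$seed, paste0("ensemble_repeat_", r)))
    runs[[r]] <- train_once(pos, tracks, genome,
      excl = excl,
      config = config, query_features = query_features
    )
  }
  scores <- NULL
  if (!is.null(query_features)) {
    per_rep <- purrr::map(runs, ~ .x$scores$score)
    scores <- tibble::tibble(region_id = runs[[1]]$scores$region_id)
    for (r in seq_len(config$repeats)) {
      scores[[paste0("score_rep", r)]] <- per_rep[[r]]
    }
    scores$mean_score <- rowMeans(as.matrix(scores[, -1, drop = FALSE]))
    scores$is_enhancer <- classify(scores$mean_score, config$threshold)
  }
  structure(
    list(
      scores = scores,
      accuracies = vapply(runs, `[[`, numeric(1), "accuracy"),
      lambdas = vapply(runs, function(x) x$cv$lambda_min, numeric(1)),
      fits = purrr::map(runs, "fit"),
      config = config
    ),
    class = "ensemble_score"
  )
}

#' @export
print.ensemble_score <- function(x, ...) {
  cat(
    "<ensemble_score>", x$config$repeats, "repeats; test accuracy",
    sprintf("%.3f +/- %.3f", mean(x$accuracies), stats::sd(x$accuracies)), "\n"
  )
  if (!is.null(x$scores)) {
    cat(
      " ", nrow(x$scores), "queries scored;",
      sum(x$scores$is_enhancer), "called enhancer\n"
    )
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ensemble_score <- function(x, ...) {
  if (is.null(x$scores)) {
    return(tibble::tibble(
      region_id = character(), mean_score = numeric(),
      is_enhancer = logical()
    ))
  }
  x$scores
}

#' @exportS3Method generics::glance
glance.ensemble_score <- function(x, ...) {
  tibble::tibble(
    repeats = x$config$repeats,
    threshold = x$config$threshold,
    mean_accuracy = mean(x$accuracies),
    sd_accuracy = stats::sd(x$accuracies),
    n_queries = if (is.null(x$scores)) 0L else nrow(x$scores),
    n_called = if (is.null(x$scores)) 0L else sum(x$scores$is_enhancer)
  )
}

#' Histogram of ensemble enhancer scores
#'
#' @param object An `ensemble_score` with scored queries.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_score <- function(object, ...) {
  stopifnot(!is.null(object$scores))
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$mean_score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(
      xintercept = object$config$threshold,
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "mean ensemble enhancer score",
      y = "regions",
      title = "Ensemble enhancer probability scores"
    )
}

#' Serialize a lasso fit to JSON (and back)
#'
#' The dump stores column names, intercept, coefficients, penalty and the
#' standardization parameters, so a model can be reloaded and applied without
#' refitting.
#'
#' @param fit A `lasso_fit`.
#' @param path Output path.
#' @return `read_lasso_fit()` returns a `lasso_fit`.
#' @export
write_lasso_fit <- function(fit, path) {
  jsonlite::write_json(
    list(
      intercept = fit$intercept,
      beta = as.list(fit$beta),
      lambda = fit$lambda,
      center = as.list(stats::setNames(fit$center, names(fit$beta))),
      scale = as.list(stats::setNames(fit$scale, names(fit$beta))),
      n_train = fit$n_train
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_lasso_fit
#' @export
read_lasso_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      intercept = x$intercept,
      beta = unlist(x$beta),
      lambda = x$lambda,
      center = unlist(x$center),
      scale = unlist(x$scale),
      n_train = x$n_train
    ),
    class = "lasso_fit"
  )
}
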