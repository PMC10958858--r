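#' Seeded age-stratified fold assignment
#'
#' Assigns cross-validation folds so that each fold spans the age range:
#' within every age group samples are randomly permuted (seeded) and dealt
#' to folds cyclically. With few samples and few ages this prevents
#' age-degenerate folds.
#'
#' @param ages Vector of chronological ages.
#' @param cv_folds Number of folds.
#' @param seed Seed.
#' @return Integer fold id per sample.
#' @export
stratified_folds <- function(ages, cv_folds, seed) {
  set.seed(seed)
  fold <- integer(length(ages))
  offset <- 0L
  for (a in sort(unique(ages))) {
    idx <- which(ages == a)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% cv_folds) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Fit an elastic-net epigenetic clock
#'
#' Regresses chronological age on per-CpG methylation fractions with the
#' elastic-net penalty `lambda * (alpha * |beta|_1 + (1-alpha)/2 * |beta|_2^2)`
#' over a descending lambda path (glmnet). The penalty is chosen as the
#' cross-validated mean-squared-error minimizer over a seeded,
#' age-stratified fold assignment; features are standardized internally and
#' coefficients returned on the original scale. The clock's CpGs are the
#' nonzero-coefficient support at the selected penalty.
#'
#' @param X Samples x CpGs matrix of methylation fractions (no missing
#'   values; column names are the site keys).
#' @param ages Chronological ages in days, non-constant.
#' @param alpha Elastic-net mixing in `[0, 1]` (default 0.5).
#' @param cv_folds Cross-validation folds (default 3).
#' @param seed Seed for the fold assignment.
#' @param lambda Optional fixed penalty; skips cross-validation (`lambda =
#'   NULL`, the default, selects by CV; `lambda = "max"` takes the largest
#'   path value, i.e. the fully penalized model).
#' @return Object of class `epi_clock`: `sites`, `weights`, `intercept`,
#'   `alpha`, `lambda`, `cv_folds`, `seed`, plus the CV predictions
#'   (`cv_predicted`) when CV was run.
#' @export
fit_elastic_net <- function(X, ages, alpha = 0.5, cv_folds = 3, seed = 1,
                            lambda = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing methylation fractions in X")
  if (length(unique(ages)) < 2L) stop("ages must not be constant")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  cv_predicted <- NULL
  if (is.null(lambda)) {
    if (cv_folds > nrow(X)) stop("cv_folds exceeds the number of samples")
    foldid <- stratified_folds(ages, cv_folds, seed)
    cv <- glmnet::cv.glmnet(X, ages, alpha = alpha, foldid = foldid,
                            keep = TRUE, standardize = TRUE)
    lambda_sel <- cv$lambda.min
    fit <- cv$glmnet.fit
    cv_predicted <- drop(cv$fit.preval[, match(lambda_sel, cv$lambda)])
    names(cv_predicted) <- rownames(X)
    cf <- stats::coef(fit, s = lambda_sel)
  } else {
    fit <- glmnet::glmnet(X, ages, alpha = alpha, standardize = TRUE,
                          thresh = 1e-12)
    # glmnet standardizes the gaussian response internally, which divides the
    # supplied penalty by sd(y); rescale so `lambda` refers to the objective
    # (1/2n)*RSS + lambda*(alpha*|b|_1 + (1-alpha)/2*|b|_2^2) as documented
    sy <- sqrt(mean((ages - mean(ages))^2))
    lambda_sel <- if (identical(lambda, "max")) fit$lambda[1L] else lambda * sy
    cf <- stats::coef(fit, s = lambda_sel, exact = TRUE, x = X, y = ages,
                      alpha = alpha, standardize = TRUE, thresh = 1e-12)
    lambda_sel <- if (identical(lambda, "max")) fit$lambda[1L] else lambda
  }
  cf <- as.matrix(cf)
  w <- cf[-1L, 1L]
  nz <- which(w != 0)
  structure(list(sites = colnames(X)[nz], weights = w[nz],
                 intercept = cf[1L, 1L], alpha = alpha, lambda = lambda_sel,
                 cv_folds = if (is.null(lambda)) cv_folds else NA_integer_,
                 seed = seed, cv_predicted = cv_predicted),
            class = "epi_clock")
}

#' @exportS3Method base::print
print.epi_clock <- function(x, ...) {
  cat(sprintf("elastic-net epigenetic clock: %d CpGs, alpha = %g, lambda = %.4g\n",
              length(x$sites), x$alpha, x$lambda))
  invisible(x)
}

#' Predict epigenetic age
#'
#' Affine in the input fractions: `intercept + X[, sites] %*% weights`.
#'
#' @param model An `epi_clock`.
#' @param X Samples x CpGs fraction matrix containing the model's sites.
#' @return Named vector of epigenetic ages in days.
#' @export
predict_age <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model$sites, colnames(X))
  if (length(missing) > 0L) {
    stop("model features missing from X: ", paste(utils::head(missing, 3), collapse = ", "))
  }
  pred <- model$intercept +
    if (length(model$sites) > 0L) drop(X[, model$sites, drop = FALSE] %*% model$weights) else 0
  if (length(pred) == 1L && nrow(X) > 1L) pred <- rep(pred, nrow(X))
  stats::setNames(as.numeric(pred), rownames(X))
}

#' Evaluate clock predictions
#'
#' Spearman rank correlation (average ranks for ties; p from the t
#' approximation) and root-mean-square error in days between epigenetic and
#' chronological age.
#'
#' @param predicted,chronological Equal-length vectors, n >= 3.
#' @return List with `spearman_rho`, `spearman_p`, `rmse_days`, `n`.
#' @export
evaluate_clock <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) stop("length mismatch")
  n <- length(predicted)
  if (n < 3L) stop("need at least 3 samples")
  rho <- stats::cor(rank(predicted), rank(chronological))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  list(spearman_rho = rho, spearman_p = p,
       rmse_days = sqrt(mean((predicted - chronological)^2)), n = n)
}

#' Age acceleration residuals
#'
#' The residuals of an ordinary least-squares regression of chronological
#' age on epigenetic age (intercept included); positive values mark samples
#' biologically "older" than their epigenetic age predicts. Residuals sum to
#' zero by construction.
#'
#' @param predicted Epigenetic ages (non-constant).
#' @param chronological Chronological ages, same length >= 3.
#' @return Vector of residuals in days.
#' @export
age_acceleration <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) stop("length mismatch")
  if (length(predicted) < 3L) stop("need at least 3 samples")
  if (stats::sd(predicted) == 0) stop("constant predictions: acceleration undefined")
  stats::resid(stats::lm(chronological ~ predicted))
}

#' Wilcoxon rank-sum test of two residual groups
#'
#' `W` is group A's rank sum (average ranks) minus `n_A (n_A + 1) / 2`. The
#' two-sided p-value is exact (enumeration) when `n_A + n_B <= 12` and there
#' are no ties, and uses the normal approximation with tie correction (and
#' continuity correction) otherwise.
#'
#' @param groupA,groupB Non-empty numeric vectors.
#' @return List with `W` and `p`.
#' @export
rank_sum_test <- function(groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L) stop("empty group")
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  exact <- (length(groupA) + length(groupB)) <= 12L && !ties
  ht <- suppressWarnings(stats::wilcox.test(groupA, groupB, exact = exact,
                                            correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value)
}
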