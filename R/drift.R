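#' Map proportions on [0,1] into the open interval (0,1)
#'
#' Standard compression for boundary responses before beta-likelihood
#' fitting: `y' = (y * (n - 1) + 0.5) / n`. Affine, hence monotone and
#' order-preserving.
#'
#' @param y Proportions in `[0, 1]`.
#' @param n Number of observations in the fit (default `length(y)`).
#' @return Transformed values strictly inside (0, 1) for `n >= 1`.
#' @export
boundary_transform <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1)) stop("proportions must lie in [0, 1]")
  (y * (n - 1) + 0.5) / n
}

beta_negloglik <- function(theta, y, X) {
  k <- ncol(X)
  mu <- stats::plogis(drop(X %*% theta[seq_len(k)]))
  phi <- exp(theta[k + 1L])
  a <- mu * phi
  b <- (1 - mu) * phi
  -sum(lgamma(phi) - lgamma(a) - lgamma(b) +
         (a - 1) * log(y) + (b - 1) * log1p(-y))
}

beta_negloglik_grad <- function(theta, y, X) {
  k <- ncol(X)
  eta <- drop(X %*% theta[seq_len(k)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[k + 1L])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dbeta <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                (1 - mu) * digamma((1 - mu) * phi) +
                mu * log(y) + (1 - mu) * log1p(-y))
  -c(dbeta, dphi * phi)
}

#' Beta regression with logit link and constant precision
#'
#' Maximum-likelihood fit of the beta density parameterised by mean
#' `mu = logistic(X beta)` and precision `phi` (`shape1 = mu*phi`,
#' `shape2 = (1-mu)*phi`) — the workhorse for modelling methylation
#' proportions and entropy against age and sex. Wald standard errors come
#' from the observed information at the optimum. Responses on the boundary
#' must be compressed first (see [boundary_transform()]); the fit refuses
#' them otherwise.
#'
#' @param y Responses strictly in (0, 1).
#' @param X Design matrix (including the intercept column), full rank.
#' @param max_iter BFGS iteration cap.
#' @return Object of class `betareg_fit`: `coef`, `se`, `phi`, `loglik`,
#'   `converged`, `fitted`, `n`.
#' @export
fit_beta_regression <- function(y, X, max_iter = 200) {
  X <- as.matrix(X)
  if (any(y <= 0 | y >= 1)) {
    stop("responses must be strictly inside (0,1); apply boundary_transform first")
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (length(y) <= ncol(X) + 1L) stop("need n > ncol(X) + 1 observations")
  # start at the OLS fit on the logit scale, moment estimate for phi
  z <- stats::qlogis(y)
  beta0 <- qr.solve(X, z)
  mu0 <- stats::plogis(drop(X %*% beta0))
  s2 <- max(stats::var(y - mu0), 1e-8)
  phi0 <- max(mean(mu0 * (1 - mu0)) / s2 - 1, 1.1)
  theta0 <- c(beta0, log(phi0))
  opt <- stats::optim(theta0, beta_negloglik, beta_negloglik_grad,
                      y = y, X = X, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  k <- ncol(X)
  hess <- try(stats::optimHess(opt$par, beta_negloglik, beta_negloglik_grad,
                               y = y, X = X), silent = TRUE)
  se <- rep(NA_real_, k)
  ok_hess <- FALSE
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc)[seq_len(k)] > 0)) {
      se <- sqrt(diag(vc)[seq_len(k)])
      ok_hess <- TRUE
    }
  }
  coef <- opt$par[seq_len(k)]
  names(coef) <- colnames(X)
  names(se) <- colnames(X)
  structure(list(coef = coef, se = se, phi = exp(opt$par[k + 1L]),
                 loglik = -opt$value,
                 converged = opt$convergence == 0L && ok_hess &&
                   is.finite(opt$value),
                 fitted = stats::plogis(drop(X %*% coef)),
                 n = length(y)),
            class = "betareg_fit")
}

#' @exportS3Method base::print
print.betareg_fit <- function(x, ...) {
  cat("beta regression (logit link), n =", x$n,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(data.frame(estimate = x$coef, se = x$se,
                   z = x$coef / x$se, row.names = names(x$coef)))
  cat(sprintf("precision phi = %.4g, log-likelihood = %.4f\n", x$phi, x$loglik))
  invisible(x)
}

ols_fit <- function(y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qx, y)
  list(beta = beta, resid = y - drop(X %*% beta))
}

#' Breusch-Pagan heteroscedasticity test (studentized form)
#'
#' Ordinary least squares of `y` on `X`, then an auxiliary regression of the
#' squared residuals on the same design; the Koenker (studentized) Lagrange
#' multiplier statistic is `n * R_aux^2`, referred to chi-square with
#' degrees of freedom equal to the number of non-intercept columns. When the
#' first regression has zero residual variance the statistic is 0 and p = 1.
#'
#' @param y Response vector.
#' @param X Design matrix including the intercept column.
#' @return List with `bp_stat`, `df`, `p`.
#' @export
breusch_pagan <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  if (n <= ncol(X) + 1L) stop("need n > ncol(X) + 1 observations")
  f1 <- ols_fit(y, X)
  u <- f1$resid^2
  sst <- sum((u - mean(u))^2)
  df <- ncol(X) - 1L
  if (sst <= .Machine$double.eps * max(u, 1)^2 * n) {
    return(list(bp_stat = 0, df = df, p = 1))
  }
  f2 <- ols_fit(u, X)
  r2 <- 1 - sum(f2$resid^2) / sst
  stat <- n * r2
  list(bp_stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

drift_design <- function(sheet) {
  cbind(`(Intercept)` = 1, age = sheet$age_days,
        sexM = as.numeric(sheet$sex == "M"))
}

#' Detect variably methylated positions
#'
#' Screens every methylated CpG for age-related epigenetic drift: per site,
#' methylation fractions are computed and boundary-transformed, a beta
#' regression on age + sex is fitted and recorded (sites whose fit does not
#' converge are excluded from testing), and the Breusch-Pagan test is run on
#' the linear fit of the fractions on (age, sex). Holm-Bonferroni adjustment
#' is applied across all tested sites; a site is a VMP when its adjusted p
#' falls below `alpha`.
#'
#' @param mat `meth_matrix` restricted to methylated sites (>= 6 samples).
#' @param alpha Family-wise threshold (default 0.05).
#' @param fit_beta Fit and record the per-site beta regression? Default
#'   `TRUE`, matching the screening procedure; set `FALSE` to run only the
#'   heteroscedasticity test.
#' @return Data frame `site_key, bp_stat, df, p, p_holm, is_vmp,
#'   beta_converged` (the latter `NA` when `fit_beta = FALSE`).
#' @export
detect_vmps <- function(mat, alpha = 0.05, fit_beta = TRUE) {
  sheet <- mat$samples
  if (nrow(sheet) < 6L) stop("need at least 6 samples")
  X <- drift_design(sheet)
  frac <- meth_fractions(mat)
  n_samp <- ncol(frac)
  keys <- rownames(frac)
  res <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    y <- boundary_transform(frac[i, ], n = n_samp)
    conv <- NA
    if (fit_beta) {
      fit <- try(fit_beta_regression(y, X), silent = TRUE)
      conv <- !inherits(fit, "try-error") && fit$converged
    }
    if (isFALSE(conv)) {
      res[[i]] <- data.frame(site_key = keys[i], bp_stat = NA_real_,
                             df = NA_integer_, p = NA_real_,
                             beta_converged = FALSE)
    } else {
      bp <- breusch_pagan(y, X)
      res[[i]] <- data.frame(site_key = keys[i], bp_stat = bp$bp_stat,
                             df = bp$df, p = bp$p, beta_converged = conv)
    }
  }
  out <- do.call(rbind, res)
  tested <- !is.na(out$p)
  out$p_holm <- NA_real_
  out$p_holm[tested] <- stats::p.adjust(out$p[tested], method = "holm")
  out$is_vmp <- !is.na(out$p_holm) & out$p_holm < alpha
  out[, c("site_key", "bp_stat", "df", "p", "p_holm", "is_vmp", "beta_converged")]
}

#' Normalized Shannon entropy of methylation fractions
#'
#' Mean binary entropy of the per-CpG methylation fractions, normalized to
#' `[0, 1]`:
#' `entropy = 1/(N * ln(1/2)) * sum_i [MF_i ln MF_i + (1 - MF_i) ln(1 - MF_i)]`
#' with the convention `0 * ln 0 = 0`. 0 means a fully determined methylome
#' (all fractions at 0 or 1), 1 a maximally noisy one (all at 0.5). The
#' `"printed"` variant replaces the second term by
#' `(1 - MF_i) * (1 - ln MF_i)`; it is provided for comparison only and is
#' not bounded to `[0, 1]`.
#'
#' @param mf Vector of methylation fractions in `[0, 1]`.
#' @param variant `"binary"` (default) or `"printed"`.
#' @return The entropy value.
#' @export
shannon_entropy <- function(mf, variant = c("binary", "printed")) {
  variant <- match.arg(variant)
  if (length(mf) == 0L) stop("empty methylation-fraction vector")
  if (any(mf < 0 | mf > 1)) stop("methylation fractions must lie in [0, 1]")
  xlx <- function(x) ifelse(x == 0, 0, x * log(x))
  terms <- if (variant == "binary") {
    xlx(mf) + xlx(1 - mf)
  } else {
    xlx(mf) + (1 - mf) * (1 - log(mf))
  }
  sum(terms) / (length(mf) * log(0.5))
}

#' Per-sample methylome entropy over a site set
#'
#' Computes each sample's normalized Shannon entropy over a fixed set of
#' CpGs (typically the age-significant differentially methylated set).
#'
#' @param mat A united `meth_matrix` covering `site_keys` in every sample.
#' @param site_keys Non-empty character vector of `chrom:pos` keys.
#' @return Data frame `sample_id, entropy, n_sites`.
#' @export
entropy_per_sample <- function(mat, site_keys) {
  if (length(site_keys) == 0L) stop("empty site set")
  missing <- setdiff(site_keys, rownames(mat$meth))
  if (length(missing) > 0L) {
    stop("site set not in matrix: ", paste(utils::head(missing, 3), collapse = ", "))
  }
  sub <- subset_sites(mat, site_keys)
  frac <- meth_fractions(sub)
  data.frame(sample_id = colnames(frac),
             entropy = apply(frac, 2, shannon_entropy),
             n_sites = nrow(frac),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Entropy ageing model: age x sex beta regression
#'
#' Fits a beta regression of per-sample entropy on age, sex and their
#' interaction, tests the interaction by a likelihood-ratio chi-square
#' (1 df), and runs post-hoc per-sex slope tests by refitting within each
#' sex and Wald-testing the age coefficient.
#'
#' @param entropies Output of [entropy_per_sample()].
#' @param sheet Sample sheet with `sample_id, sex, age_days`.
#' @return List of class `entropy_model`: `interaction_chisq`,
#'   `interaction_df`, `interaction_p`, `full` (the full `betareg_fit`),
#'   `per_sex` (data frame `sex, slope, se, z, p`).
#' @export
entropy_age_model <- function(entropies, sheet) {
  d <- merge(entropies, sheet[, c("sample_id", "sex", "age_days")],
             by = "sample_id")
  if (min(table(d$sex)) < 2L) stop("need >= 2 entropy values per sex")
  y <- d$entropy
  if (any(y <= 0 | y >= 1)) y <- boundary_transform(y)
  sexM <- as.numeric(d$sex == "M")
  X_full <- cbind(`(Intercept)` = 1, age = d$age_days, sexM = sexM,
                  `age:sexM` = d$age_days * sexM)
  X_red <- X_full[, 1:3, drop = FALSE]
  fit_full <- fit_beta_regression(y, X_full)
  fit_red <- fit_beta_regression(y, X_red)
  lr <- max(0, 2 * (fit_full$loglik - fit_red$loglik))
  per_sex <- lapply(unique(d$sex), function(s) {
    di <- d[d$sex == s, , drop = FALSE]
    if (length(unique(di$age_days)) < 3L) {
      warning("fewer than 3 distinct ages for sex ", s, "; slope test skipped")
      return(data.frame(sex = s, slope = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_))
    }
    yi <- di$entropy
    if (any(yi <= 0 | yi >= 1)) yi <- boundary_transform(yi)
    fi <- fit_beta_regression(yi, cbind(`(Intercept)` = 1, age = di$age_days))
    z <- fi$coef[["age"]] / fi$se[["age"]]
    data.frame(sex = s, slope = fi$coef[["age"]], se = fi$se[["age"]],
               z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  structure(list(interaction_chisq = lr, interaction_df = 1L,
                 interaction_p = stats::pchisq(lr, 1, lower.tail = FALSE),
                 full = fit_full,
                 per_sex = do.call(rbind, per_sex)),
            class = "entropy_model")
}

#' @exportS3Method base::print
print.entropy_model <- function(x, ...) {
  cat(sprintf("entropy ~ age * sex beta regression\ninteraction LR chi-square = %.4f, df = %d, p = %.4g\n",
              x$interaction_chisq, x$interaction_df, x$interaction_p))
  cat("per-sex age slopes (Wald):\n")
  print(x$per_sex, row.names = FALSE)
  invisible(x)
}
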