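# Sensitivity/specificity as an intercept-only logistic marginal model with
# exchangeable working correlation, fitted by generalized estimating
# equations. With clusters i of size n_i, working correlation alpha and
# p = expit(beta), the estimating equation
#   sum_i 1' R_i^{-1} (y_i - p 1) = 0
# collapses (since R_i^{-1} 1 = 1 / (1 + (n_i - 1) alpha)) to the weighted
# mean  p = sum_i w_i ybar_i / sum_i w_i  with  w_i = n_i / (1 + (n_i-1) alpha).
# alpha is re-estimated from Pearson residual cross-products each iteration,
# and the variance of beta-hat is the robust sandwich
#   B^{-1} M B^{-1},  B = p(1-p) sum_i w_i,
#   M = sum_i (S_i - n_i p)^2 / (1 + (n_i - 1) alpha)^2,  S_i = sum_j y_ij.

#' Wald confidence interval for a proportion
#'
#' Symmetric on the logit scale and back-transformed (default), or on the
#' linear (response) scale clipped to the unit interval.
#'
#' @param beta intercept on the logit scale.
#' @param se standard error of `beta` (logit scale). For `scale = "linear"`,
#'   the standard error is first mapped to the response scale by the delta
#'   method.
#' @param conf_level confidence level, default 0.95.
#' @param scale `"logit"` (default) or `"linear"`.
#' @return numeric `c(low, high)`.
#' @export
wald_ci <- function(beta, se, conf_level = 0.95, scale = c("logit", "linear")) {
  scale <- match.arg(scale)
  if (!is.finite(beta) || !is.finite(se) || se < 0)
    abort_parameter("wald_ci: beta and se must be finite, se non-negative")
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (scale == "logit") {
    c(low = expit(beta - z * se), high = expit(beta + z * se))
  } else {
    p <- expit(beta)
    sp <- p * (1 - p) * se
    c(low = max(0, p - z * sp), high = min(1, p + z * sp))
  }
}

new_accuracy_estimate <- function(measure, estimate, se, ci, method,
                                  n_units, n_clusters, fit = NULL,
                                  degenerate = FALSE) {
  structure(list(measure = measure, estimate = estimate, se = se,
                 ci = c(low = unname(ci[1]), high = unname(ci[2])),
                 method = method, n_units = n_units, n_clusters = n_clusters,
                 fit = fit, degenerate = degenerate),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("%s (%s): %.3f [%.3f, %.3f]%s  (n=%d units, %d clusters)\n",
              x$measure, x$method, x$estimate, x$ci[1], x$ci[2],
              if (x$degenerate) " [degenerate]" else "",
              x$n_units, x$n_clusters))
  invisible(x)
}

#' Crude (independence) proportion estimate
#'
#' Baseline against which the GEE estimate is compared: the plain cell
#' ratio with binomial standard error and a logit-scale Wald interval.
#'
#' @param numerator,denominator cell counts (e.g. TP and TP+FN for
#'   sensitivity).
#' @param measure label, e.g. `"sensitivity"`.
#' @param conf_level confidence level.
#' @param ci_scale passed to [wald_ci()].
#' @return an `accuracy_estimate` with `method = "crude"`.
#' @export
crude_estimate <- function(numerator, denominator, measure = "proportion",
                           conf_level = 0.95, ci_scale = "logit") {
  if (denominator <= 0) abort_estimation("crude_estimate: zero denominator")
  if (numerator < 0 || numerator > denominator)
    abort_parameter("numerator must lie in [0, denominator]")
  p <- numerator / denominator
  se <- sqrt(p * (1 - p) / denominator)
  if (numerator == 0 || numerator == denominator) {
    return(new_accuracy_estimate(measure, p, 0, c(p, p), "crude",
                                 denominator, denominator, degenerate = TRUE))
  }
  se_beta <- 1 / sqrt(denominator * p * (1 - p))
  ci <- wald_ci(logit(p), se_beta, conf_level, ci_scale)
  new_accuracy_estimate(measure, p, se, ci, "crude", denominator, denominator)
}

#' Intercept-only logistic GEE with exchangeable working correlation
#'
#' Estimates a marginal proportion from clustered binary outcomes
#' (patient-days or stay assessment units clustered within patients) with a
#' robust sandwich standard error and a Wald interval on the logit scale,
#' back-transformed. Fitted by fixed-point iteration between the closed-form
#' weighted-mean solution of the estimating equation and the moment estimate
#' of the working correlation.
#'
#' All-identical outcomes return the boundary estimate 0 or 1 with a flagged
#' degenerate interval instead of raising (needed e.g. for a perfect
#' detector).
#'
#' @param outcome binary (0/1 or logical) outcome vector.
#' @param cluster cluster identifiers, same length.
#' @param measure label carried into the result.
#' @param conf_level confidence level, default 0.95.
#' @param ci_scale `"logit"` (default) or `"linear"`.
#' @param max_iter,tol fixed-point iteration controls.
#' @return an `accuracy_estimate` with `method = "gee"`; its `fit` element is
#'   a `gee_fit` list: `beta`, `alpha`, `sandwich_se`, `converged`,
#'   `iterations`, `ee_residual` (value of the estimating equation at the
#'   solution).
#' @export
gee_estimate <- function(outcome, cluster, measure = "proportion",
                         conf_level = 0.95, ci_scale = "logit",
                         max_iter = 100, tol = 1e-12) {
  y <- as.numeric(outcome)
  if (length(y) < 2) abort_estimation("gee_estimate: need at least 2 units")
  if (length(y) != length(cluster)) abort_parameter("outcome/cluster length mismatch")
  if (any(is.na(y)) || any(!y %in% c(0, 1)))
    abort_parameter("outcome must be binary with no missing values")
  cl <- as.character(cluster)
  n_i <- tapply(y, cl, length)
  S_i <- tapply(y, cl, sum)
  n_clusters <- length(n_i)
  N <- length(y)

  if (all(y == y[1])) {
    p <- y[1]
    return(new_accuracy_estimate(measure, p, 0, c(p, p), "gee", N, n_clusters,
                                 fit = list(beta = if (p == 1) Inf else -Inf,
                                            alpha = 0, sandwich_se = NA_real_,
                                            converged = TRUE, iterations = 0,
                                            ee_residual = 0),
                                 degenerate = TRUE))
  }

  npairs <- sum(n_i * (n_i - 1)) / 2
  alpha <- 0
  p <- mean(y)
  iterations <- 0
  converged <- FALSE
  alpha_hi <- 1 - 1e-6
  alpha_lo <- if (max(n_i) > 1) -1 / (max(n_i) - 1) + 1e-6 else -1 + 1e-6
  repeat {
    iterations <- iterations + 1
    w <- n_i / (1 + (n_i - 1) * alpha)
    p_new <- sum(w * (S_i / n_i)) / sum(w)
    # moment estimator of alpha from Pearson residual cross-products
    if (npairs > 1) {
      v <- p_new * (1 - p_new)
      sum_e <- (S_i - n_i * p_new) / sqrt(v)     # per-cluster residual sums
      sum_e2 <- (S_i * (1 - p_new)^2 + (n_i - S_i) * p_new^2) / v
      cross <- sum(sum_e^2 - sum_e2) / 2
      alpha_new <- cross / (npairs - 1)          # 1 mean parameter
      alpha_new <- min(max(alpha_new, alpha_lo), alpha_hi)
    } else alpha_new <- 0
    done <- abs(p_new - p) < tol && abs(alpha_new - alpha) < tol
    p <- p_new; alpha <- alpha_new
    if (done) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  # final mean update at the converged alpha so the estimating equation is
  # satisfied exactly
  w <- n_i / (1 + (n_i - 1) * alpha)
  p <- sum(w * (S_i / n_i)) / sum(w)
  ee <- sum((S_i - n_i * p) / (1 + (n_i - 1) * alpha))
  if (!converged && abs(ee) > 1e-8)
    abort_estimation(sprintf(
      "GEE did not converge after %d iterations (residual %.3g)", iterations, ee))

  beta <- logit(p)
  B <- p * (1 - p) * sum(w)
  M <- sum(((S_i - n_i * p) / (1 + (n_i - 1) * alpha))^2)
  sandwich_se <- sqrt(M) / B
  ci <- wald_ci(beta, sandwich_se, conf_level, ci_scale)
  fit <- list(beta = beta, alpha = alpha, sandwich_se = sandwich_se,
              converged = converged, iterations = iterations, ee_residual = ee)
  new_accuracy_estimate(measure, p, p * (1 - p) * sandwich_se, ci, "gee",
                        N, n_clusters, fit = fit)
}

#' Sample size for a one-sample proportion test
#'
#' Normal-approximation (chi-square-equivalent) formula without continuity
#' correction:
#' `n = ceil((z_{1-alpha/2} sqrt(p0 q0) + z_{power} sqrt(p1 q1))^2 / (p1 - p0)^2)`.
#'
#' @param p0 null-hypothesis proportion.
#' @param p1 alternative-hypothesis proportion.
#' @param alpha two-sided type-I error, default 0.05.
#' @param power target power, default 0.90.
#' @return integer sample size.
#' @export
sample_size_one_proportion <- function(p0, p1, alpha = 0.05, power = 0.90) {
  for (v in c(p0, p1, alpha, power))
    if (!is.numeric(v) || v <= 0 || v >= 1)
      abort_parameter("p0, p1, alpha and power must lie strictly in (0, 1)")
  if (p0 == p1) abort_parameter("p0 and p1 must differ")
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  n <- (za * sqrt(p0 * (1 - p0)) + zb * sqrt(p1 * (1 - p1)))^2 / (p1 - p0)^2
  as.integer(ceiling(round(n, 10)))
}
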