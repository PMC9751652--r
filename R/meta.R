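#' Fixed-effects inverse-variance meta-analysis of log hazard ratios
#'
#' Pools per-cohort coefficients by weighting each by the inverse of its
#' variance: \eqn{w_i = 1/se_i^2}, pooled coefficient
#' \eqn{\sum w_i \beta_i / \sum w_i}, pooled SE \eqn{(\sum w_i)^{-1/2}}.
#' The pooled risk ratio is the exponential of the weighted mean
#' coefficient. Heterogeneity is assessed by Cochran's
#' \eqn{Q = \sum w_i (\beta_i - \bar\beta)^2} and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100} (0 when \eqn{Q = 0}).
#'
#' @param beta numeric vector of per-cohort log hazard ratios (per SD), or a
#'   list of [gradient_of_risk()] objects.
#' @param se standard errors (ignored when \code{beta} is a list of
#'   \code{gradient_of_risk} objects).
#' @param labels optional cohort labels.
#' @param level confidence level for the pooled interval.
#' @return object of class \code{gr_meta}: \code{beta_pooled},
#'   \code{se_pooled}, \code{hr}, \code{ci_low}, \code{ci_high}, \code{p}
#'   (two-sided normal), \code{q}, \code{i2} (percent), \code{k},
#'   \code{weights}, \code{method}.
#' @examples
#' m <- pool_fixed_effects(c(log(0.7), log(0.9)), c(0.1, 0.1))
#' m$hr                      # sqrt(0.7 * 0.9)
#' @seealso [pool_random_effects()] for the DerSimonian-Laird sensitivity
#'   pooling.
#' @export
pool_fixed_effects <- function(beta, se = NULL, labels = NULL,
                               level = 0.95) {
  est <- as_meta_inputs(beta, se, labels)
  pool_meta(est$beta, est$se, est$labels, level, method = "fixed")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Random-effects counterpart of [pool_fixed_effects()], provided as a
#' labeled sensitivity output: the between-cohort variance \eqn{\tau^2} is
#' the DerSimonian-Laird moment estimator
#' \eqn{\max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i))} and the
#' weights become \eqn{1/(se_i^2 + \tau^2)}.
#'
#' @inheritParams pool_fixed_effects
#' @return object of class \code{gr_meta} with \code{method = "random"} and
#'   a \code{tau2} field.
#' @export
pool_random_effects <- function(beta, se = NULL, labels = NULL,
                                level = 0.95) {
  est <- as_meta_inputs(beta, se, labels)
  pool_meta(est$beta, est$se, est$labels, level, method = "random")
}

as_meta_inputs <- function(beta, se, labels) {
  if (is.list(beta) && all(vapply(beta, inherits, TRUE, "gradient_of_risk"))) {
    if (is.null(labels)) labels <- names(beta)
    se <- vapply(beta, function(g) g$se, 1)
    beta <- vapply(beta, function(g) g$beta, 1)
  }
  k <- length(beta)
  if (k < 1L) stop("meta-analysis requires at least one estimate")
  if (length(se) != k) stop("beta and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("meta-analysis requires all se > 0")
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  list(beta = as.numeric(beta), se = as.numeric(se), labels = labels)
}

pool_meta <- function(beta, se, labels, level, method) {
  k <- length(beta)
  w_fe <- 1 / se^2
  bp_fe <- sum(w_fe * beta) / sum(w_fe)
  q <- sum(w_fe * (beta - bp_fe)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  tau2 <- 0
  if (method == "random" && k > 1L) {
    denom <- sum(w_fe) - sum(w_fe^2) / sum(w_fe)
    if (denom > 0) tau2 <- max(0, (q - (k - 1)) / denom)
  }
  w <- 1 / (se^2 + tau2)
  bp <- sum(w * beta) / sum(w)
  sp <- 1 / sqrt(sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(beta_pooled = bp, se_pooled = sp,
                 hr = exp(bp), ci_low = exp(bp - z * sp),
                 ci_high = exp(bp + z * sp),
                 p = 2 * stats::pnorm(-abs(bp / sp)),
                 q = q, i2 = i2, tau2 = tau2, k = k,
                 weights = stats::setNames(w / sum(w), labels),
                 beta = stats::setNames(beta, labels),
                 se = stats::setNames(se, labels),
                 level = level, method = method),
            class = "gr_meta")
}

#' @export
print.gr_meta <- function(x, ...) {
  cat(sprintf("%s-effects meta-analysis of %d cohort(s)\n",
              if (x$method == "fixed") "Fixed" else "Random (DL)", x$k))
  cat(sprintf("  pooled GR %s, p = %.3g\n", format_gr(x), x$p))
  cat(sprintf("  Q = %.3f (df = %d), I2 = %.1f%%%s\n", x$q, x$k - 1L, x$i2,
              if (x$method == "random") sprintf(", tau2 = %.4f", x$tau2)
              else ""))
  invisible(x)
}
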