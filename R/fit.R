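#' Standardize an exposure within cohorts
#'
#' Centers and scales a raw exposure within each cohort using the sample
#' mean and sample SD (denominator n - 1), so that model coefficients are
#' log hazard ratios per within-cohort SD — the scale on which the gradient
#' of risk is defined and on which per-cohort estimates are pooled. Pooled
#' (all-cohorts) standardization is available by passing a single group
#' label.
#'
#' @param values numeric vector of raw exposure values.
#' @param group cohort labels, same length as \code{values} (or length 1).
#' @return list with \code{std} (the standardized vector), \code{sd} and
#'   \code{mean} (named per-group vectors).
#' @examples
#' standardize_exposure(c(1, 2, 3), "a")$std   # -1 0 1
#' @export
standardize_exposure <- function(values, group) {
  if (length(group) == 1L) group <- rep(group, length(values))
  stopifnot(length(group) == length(values))
  g <- factor(group, levels = unique(group))
  mu <- tapply(values, g, mean)
  sd_g <- tapply(values, g, stats::sd)
  bad <- is.na(sd_g) | sd_g == 0
  if (any(bad))
    stop("standardize_exposure: zero or undefined SD in cohort(s): ",
         paste(names(sd_g)[bad], collapse = ", "))
  idx <- as.integer(g)
  list(std = as.numeric((values - mu[idx]) / sd_g[idx]),
       sd = stats::setNames(as.numeric(sd_g), names(sd_g)),
       mean = stats::setNames(as.numeric(mu), names(mu)))
}

#' Fit the Poisson hazard model on person-month data
#'
#' Maximum-likelihood fit of the piecewise-exponential (Poisson regression
#' extension) survival model on month-split person-time. The hazard is
#' \deqn{\lambda = \exp(\beta_0 + \beta_1 t + \beta_2\,\mathrm{age}(t) +
#'   \beta_3 x + \dots)}
#' with \eqn{t} the current time from baseline and age the current age, and
#' each interval contributes \eqn{y\,\eta - e^{\eta}\Delta t} to the
#' log-likelihood (\eqn{\eta} the linear predictor, \eqn{\Delta t} the
#' interval's exposure in years — equivalent to an offset of
#' \eqn{\log \Delta t}, handling the partial final month exactly).
#' Maximization is by Newton-Raphson with step-halving; the covariance is
#' the inverse observed information at the optimum. The log-likelihood is
#' concave, so the optimum is global when it exists.
#'
#' @param pm person-month data frame from [split_followup()] (columns
#'   \code{t_current}, \code{age_current}, \code{delta_t}, \code{event}).
#' @param covariates character vector of covariate column names entering the
#'   linear predictor after intercept, time and age; looked up in \code{pm},
#'   or in \code{subjects} via \code{pm$subject_row}.
#' @param subjects optional person-level table supplying covariate columns
#'   not present in \code{pm}.
#' @param base_terms which of \code{c("time", "age")} to include; the empty
#'   vector gives the intercept-only model whose MLE is
#'   \code{log(events / person-years)} in closed form.
#' @param exposure name of the covariate treated as the exposure of interest
#'   by [gradient_of_risk()] (default: the first covariate).
#' @param exposure_sd the raw-scale SD used to standardize the exposure, if
#'   any; stored for reporting.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum Newton iterations.
#' @return an object of class \code{poisson_hazard}: list with \code{beta}
#'   (named coefficients), \code{cov} (inverse observed information),
#'   \code{loglik}, \code{n_intervals}, \code{n_events},
#'   \code{person_years}, \code{converged}, \code{n_iter}, \code{exposure},
#'   \code{exposure_sd}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{vcov}, \code{logLik}, \code{confint}, \code{predict},
#'   \code{residuals}, \code{nobs}.
#' @seealso [gradient_of_risk()], [split_followup()]
#' @export
fit_poisson_hazard <- function(pm, covariates = character(),
                               subjects = NULL,
                               base_terms = c("time", "age"),
                               exposure = if (length(covariates)) covariates[1] else NA_character_,
                               exposure_sd = NA_real_,
                               tol = 1e-10, max_iter = 100L) {
  if (length(base_terms))
    base_terms <- match.arg(base_terms, c("time", "age"), several.ok = TRUE)
  y <- pm$event
  dt <- pm$delta_t
  if (any(dt <= 0)) stop("fit_poisson_hazard: non-positive delta_t")
  n_events <- sum(y)
  if (n_events < 1L) stop("fit_poisson_hazard: no events in person-month data")
  cols <- list(`(Intercept)` = rep(1, nrow(pm)))
  if ("time" %in% base_terms) cols$time <- pm$t_current
  if ("age" %in% base_terms) cols$age <- pm$age_current
  for (v in covariates) {
    cols[[v]] <- if (v %in% names(pm)) pm[[v]]
                 else if (!is.null(subjects) && v %in% names(subjects))
                   subjects[[v]][pm$subject_row]
                 else stop("fit_poisson_hazard: covariate not found: ", v)
    if (anyNA(cols[[v]]))
      stop("fit_poisson_hazard: missing values in covariate '", v,
           "'; apply complete-case filtering before splitting")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (qr(X)$rank < ncol(X))
    stop("fit_poisson_hazard: design matrix is rank deficient")

  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  beta[1] <- log(n_events / sum(dt))
  ll_fun <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - exp(eta) * dt)
  }
  ll <- ll_fun(beta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- exp(eta) * dt       # expected events per interval
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X, X * mu)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break  # singular information: separation or collapse
    # step-halving keeps the ascent monotone far from the optimum
    new_ll <- -Inf
    for (h in 0:30) {
      cand <- beta + step / 2^h
      new_ll <- ll_fun(cand)
      if (is.finite(new_ll) && new_ll >= ll - 1e-12) break
    }
    if (!is.finite(new_ll)) break
    rel <- abs(new_ll - ll) / (abs(ll) + 1e-10)
    beta <- cand
    ll <- new_ll
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- exp(eta) * dt
  info <- crossprod(X, X * mu)
  cov <- tryCatch(solve(info), error = function(e) {
    converged <<- FALSE
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, cov = cov, loglik = ll,
                 n_intervals = nrow(pm), n_events = n_events,
                 person_years = sum(dt),
                 converged = converged, n_iter = iter,
                 exposure = exposure, exposure_sd = exposure_sd,
                 call = match.call()),
            class = "poisson_hazard")
}

#' @export
coef.poisson_hazard <- function(object, ...) object$beta

#' @export
vcov.poisson_hazard <- function(object, ...) object$cov

#' @export
logLik.poisson_hazard <- function(object, ...) {
  structure(object$loglik, df = length(object$beta), class = "logLik")
}

#' @export
nobs.poisson_hazard <- function(object, ...) object$n_intervals

#' @export
confint.poisson_hazard <- function(object, parm = NULL, level = 0.95, ...) {
  se <- sqrt(diag(object$cov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - z * se, object$beta + z * se)
  dimnames(ci) <- list(names(object$beta),
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.poisson_hazard <- function(x, digits = 4, ...) {
  cat("Poisson hazard model on month-split person-time\n")
  cat(sprintf("  %d intervals, %d events, %.1f person-years\n",
              x$n_intervals, x$n_events, x$person_years))
  cat(sprintf("  log-likelihood %.4f, %s in %d iterations\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
summary.poisson_hazard <- function(object, ...) {
  se <- sqrt(diag(object$cov))
  z <- object$beta / se
  tab <- cbind(Estimate = object$beta, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 n_intervals = object$n_intervals,
                 n_events = object$n_events,
                 person_years = object$person_years,
                 converged = object$converged, exposure = object$exposure),
            class = "summary.poisson_hazard")
}

#' @export
print.summary.poisson_hazard <- function(x, ...) {
  cat("Poisson hazard model on month-split person-time\n")
  cat(sprintf("  %d intervals, %d events, %.1f person-years%s\n",
              x$n_intervals, x$n_events, x$person_years,
              if (x$converged) "" else "  [NOT converged]"))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.poisson_hazard <- function(object, newdata,
                                   type = c("hazard", "events", "link"),
                                   ...) {
  type <- match.arg(type)
  nm <- names(object$beta)
  cols <- lapply(nm, function(v) {
    if (v == "(Intercept)") rep(1, nrow(newdata))
    else if (v == "time") newdata$t_current
    else if (v == "age") newdata$age_current
    else newdata[[v]]
  })
  X <- do.call(cbind, cols)
  eta <- drop(X %*% object$beta)
  switch(type,
         link = eta,
         hazard = exp(eta),
         events = exp(eta) * newdata$delta_t)
}

#' @export
residuals.poisson_hazard <- function(object, pm, covariates = character(),
                                     type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  mu <- predict(object, pm, type = "events")
  r <- pm$event - mu
  if (type == "pearson") r <- r / sqrt(mu)
  r
}

#' Gradient of risk: hazard ratio per SD of the exposure
#'
#' Extracts the per-SD hazard ratio for the exposure of interest from a
#' converged [fit_poisson_hazard()] result, with a Wald 95% confidence
#' interval, \eqn{\exp(\beta_3 \pm z\,\mathrm{se})}, and a two-sided normal
#' p-value. Because the exposure is standardized before fitting, the
#' gradient of risk is invariant to the raw measurement units.
#'
#' @param fit a converged \code{poisson_hazard} object.
#' @param exposure coefficient name (default: the fit's stored exposure).
#' @param level confidence level.
#' @return object of class \code{gradient_of_risk}: list with \code{hr},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{beta}, \code{se},
#'   \code{exposure}, \code{level}.
#' @export
gradient_of_risk <- function(fit, exposure = fit$exposure, level = 0.95) {
  stopifnot(inherits(fit, "poisson_hazard"))
  if (!isTRUE(fit$converged))
    stop("gradient_of_risk: fit did not converge")
  if (is.na(exposure) || !exposure %in% names(fit$beta))
    stop("gradient_of_risk: exposure coefficient not found: ", exposure)
  b <- fit$beta[[exposure]]
  se <- sqrt(fit$cov[exposure, exposure])
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(hr = exp(b), ci_low = exp(b - z * se),
                 ci_high = exp(b + z * se),
                 p = 2 * stats::pnorm(-abs(b / se)),
                 beta = b, se = se, exposure = exposure, level = level),
            class = "gradient_of_risk")
}

#' Format a hazard ratio with its confidence interval
#'
#' Renders \code{"0.78 (0.66, 0.91)"}-style strings (two decimals) from a
#' [gradient_of_risk()] or [pool_fixed_effects()] result or raw numbers.
#'
#' @param hr hazard ratio (or an object with \code{hr}, \code{ci_low},
#'   \code{ci_high} fields).
#' @param ci_low,ci_high interval bounds (ignored when \code{hr} is an
#'   object).
#' @param digits decimal places.
#' @return character scalar.
#' @export
format_gr <- function(hr, ci_low = NULL, ci_high = NULL, digits = 2) {
  if (is.list(hr)) {
    ci_low <- hr$ci_low; ci_high <- hr$ci_high; hr <- hr$hr
  }
  sprintf("%.*f (%.*f, %.*f)", digits, hr, digits, ci_low, digits, ci_high)
}

#' @export
print.gradient_of_risk <- function(x, ...) {
  cat(sprintf("Gradient of risk (%s): %s, p = %.3g\n",
              x$exposure, format_gr(x), x$p))
  invisible(x)
}
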