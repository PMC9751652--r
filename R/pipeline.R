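#' Model specification for one analysis cell
#'
#' Describes one fracture-outcome / exposure / adjustment combination. The
#' base model always contains intercept, current time from baseline and
#' current age; adjusters add covariates on top.
#'
#' @param outcome one of \code{"any"}, \code{"osteoporotic"}, \code{"mof"},
#'   \code{"hip"}.
#' @param exposure \code{"csa"} (muscle cross-sectional area) or
#'   \code{"density"} (muscle density); the aliases \code{"muscle_csa"} and
#'   \code{"muscle_density"} are accepted.
#' @param adjusters subset of \code{c("fn_tscore", "frax_mof_wo",
#'   "frax_mof_w", "prior_falls", "bmi", "other_muscle")}.
#'   \code{"other_muscle"} is the other pQCT measure, standardized
#'   identically to the exposure; T-score (already in SD units), FRAX
#'   probabilities (percent), BMI and the prior-fall indicator enter
#'   untransformed.
#' @param standardize standardize the exposure within cohort (default TRUE;
#'   the gradient of risk presumes it).
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(outcome, exposure, adjusters = character(),
                       standardize = TRUE) {
  outcome <- match.arg(outcome, outcome_names())
  exposure <- switch(exposure,
                     muscle_csa = "csa", muscle_density = "density",
                     match.arg(exposure, c("csa", "density")))
  allowed <- c("fn_tscore", "frax_mof_wo", "frax_mof_w", "prior_falls",
               "bmi", "other_muscle")
  if (!all(adjusters %in% allowed))
    stop("model_spec: adjusters must be among ",
         paste(allowed, collapse = ", "))
  structure(list(outcome = outcome, exposure = exposure,
                 adjusters = unique(adjusters),
                 standardize = isTRUE(standardize)),
            class = "model_spec")
}

# subject-level column behind each adjuster label
adjuster_column <- function(adjuster, exposure) {
  switch(adjuster,
         fn_tscore = "tscore",
         frax_mof_wo = "frax_mof_wo",
         frax_mof_w = "frax_mof_w",
         prior_falls = "prior_fall",
         bmi = "bmi",
         other_muscle = if (exposure == "csa") "density" else "csa",
         stop("unknown adjuster: ", adjuster))
}

#' The standard eight-row adjustment grid
#'
#' The adjustment sets under which each exposure-outcome association is
#' reported: the base model (age and follow-up time only) and seven
#' additions — FN BMD T-score, FRAX MOF probability without and with BMD,
#' prior falls, BMI, T-score plus BMI, and the other pQCT muscle measure.
#'
#' @param exposure \code{"csa"} or \code{"density"}; only affects the label
#'   of the other-muscle-measure row.
#' @return list of rows, each with \code{label} and \code{adjusters}.
#' @export
default_adjustments <- function(exposure = "csa") {
  other_label <- if (exposure == "csa") "Base + muscle density"
                 else "Base + cross sectional area"
  list(
    list(label = "Base: Age and follow-up time", adjusters = character()),
    list(label = "Base + FN BMD T-score", adjusters = "fn_tscore"),
    list(label = "Base + FRAX MOF wo", adjusters = "frax_mof_wo"),
    list(label = "Base + FRAX MOF w", adjusters = "frax_mof_w"),
    list(label = "Base + prior falls", adjusters = "prior_falls"),
    list(label = "Base + BMI", adjusters = "bmi"),
    list(label = "Base + FN BMD T-score and BMI",
         adjusters = c("fn_tscore", "bmi")),
    list(label = other_label, adjusters = "other_muscle")
  )
}

#' Fit one model within one cohort
#'
#' Applies the full per-cohort estimation path for a [model_spec()]:
#' complete-case restriction on every required covariate (before person-time
#' splitting), within-cohort standardization of the exposure (and of the
#' other muscle measure when it is an adjuster), month-splitting of
#' follow-up for the outcome, and the Poisson hazard fit.
#'
#' @param subjects person-level data frame for a single cohort.
#' @param spec a [model_spec()].
#' @param site_map optional replacement site map.
#' @return a \code{poisson_hazard} fit whose \code{exposure} is the
#'   standardized exposure column and with added fields \code{n_subjects}
#'   (complete-case count) and \code{spec}.
#' @export
fit_cohort_model <- function(subjects, spec, site_map = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  adj_cols <- vapply(spec$adjusters, adjuster_column, "", exposure = spec$exposure)
  needed <- unique(c(spec$exposure, adj_cols))
  keep <- stats::complete.cases(subjects[, needed, drop = FALSE])
  d <- subjects[keep, , drop = FALSE]
  if (nrow(d) < 2L)
    stop("fit_cohort_model: fewer than 2 complete-case subjects")
  cov_names <- character()
  if (spec$standardize) {
    std <- standardize_exposure(d[[spec$exposure]], d$cohort)
    exp_col <- paste0(spec$exposure, "_std")
    d[[exp_col]] <- std$std
    exp_sd <- std$sd
  } else {
    exp_col <- spec$exposure
    exp_sd <- NA_real_
  }
  cov_names <- exp_col
  for (i in seq_along(spec$adjusters)) {
    a <- spec$adjusters[i]
    col <- adj_cols[i]
    if (a == "other_muscle" && spec$standardize) {
      d[[paste0(col, "_std")]] <- standardize_exposure(d[[col]], d$cohort)$std
      col <- paste0(col, "_std")
    }
    cov_names <- c(cov_names, col)
  }
  pm <- split_followup(d, spec$outcome, site_map = site_map)
  fit <- fit_poisson_hazard(pm, covariates = cov_names, subjects = d,
                            exposure = exp_col, exposure_sd = exp_sd)
  fit$n_subjects <- nrow(d)
  fit$spec <- spec
  fit
}

#' Run the full exposure-by-outcome-by-adjustment analysis grid
#'
#' For every combination of exposure, fracture outcome and adjustment row,
#' fits the Poisson hazard model separately within each cohort
#' (complete-case, within-cohort standardization, month-split person-time)
#' and pools the per-cohort exposure coefficients by fixed-effects
#' inverse-variance meta-analysis. Non-converged or failing per-cohort fits
#' are flagged and skipped in pooling with a warning.
#'
#' @param subjects person-level data frame spanning one or more cohorts.
#' @param exposures character subset of \code{c("csa", "density")}.
#' @param outcomes character subset of [outcome_names()].
#' @param adjustments list of rows as produced by [default_adjustments()];
#'   \code{NULL} uses the standard eight rows.
#' @param site_map optional replacement site map.
#' @param level confidence level.
#' @return object of class \code{gr_grid}: a data frame with one row per
#'   (exposure, adjustment, outcome) holding the pooled gradient of risk
#'   (\code{gr}, \code{ci_low}, \code{ci_high}, \code{p}), heterogeneity
#'   (\code{q}, \code{i2}), the number of pooled cohorts \code{k}, the
#'   complete-case subject count \code{n} and total events; per-cohort
#'   estimates are in \code{attr(, "cohort_estimates")}. \code{print()}
#'   renders one adjustment-by-outcome table per exposure with
#'   \code{"0.78 (0.66, 0.91)"}-style cells; \code{plot()} draws a forest
#'   plot.
#' @export
run_analysis <- function(subjects,
                         exposures = c("csa", "density"),
                         outcomes = outcome_names(),
                         adjustments = NULL,
                         site_map = NULL, level = 0.95) {
  required <- c("subject_id", "cohort", "age0", "followup",
                "fracture_events", "death_time", "loss_time")
  miss <- setdiff(required, names(subjects))
  if (length(miss))
    stop("run_analysis: missing required columns: ",
         paste(miss, collapse = ", "))
  exposures <- match.arg(exposures, c("csa", "density"), several.ok = TRUE)
  outcomes <- match.arg(outcomes, outcome_names(), several.ok = TRUE)
  cohorts <- split(subjects, subjects$cohort)
  pm_cache <- new.env(parent = emptyenv())

  rows <- list()
  per_cohort <- list()
  for (exposure in exposures) {
    adj_rows <- if (is.null(adjustments)) default_adjustments(exposure)
                else adjustments
    for (ar in adj_rows) {
      adj_cols <- vapply(ar$adjusters, adjuster_column, "",
                         exposure = exposure)
      needed <- unique(c(exposure, adj_cols))
      for (outcome in outcomes) {
        betas <- c(); ses <- c(); labs <- c()
        n_cc <- 0L; n_ev <- 0L; n_failed <- 0L
        for (cname in names(cohorts)) {
          cd <- cohorts[[cname]]
          keep <- stats::complete.cases(cd[, needed, drop = FALSE])
          d <- cd[keep, , drop = FALSE]
          key <- paste(cname, outcome,
                       paste(which(!keep), collapse = "."), sep = "|")
          pm <- pm_cache[[key]]
          if (is.null(pm)) {
            pm <- split_followup(d, outcome, site_map = site_map)
            pm_cache[[key]] <- pm
          }
          g <- tryCatch({
            dd <- d
            std <- standardize_exposure(dd[[exposure]], cname)
            exp_col <- paste0(exposure, "_std")
            dd[[exp_col]] <- std$std
            covs <- exp_col
            for (i in seq_along(ar$adjusters)) {
              col <- adj_cols[i]
              if (ar$adjusters[i] == "other_muscle") {
                dd[[paste0(col, "_std")]] <-
                  standardize_exposure(dd[[col]], cname)$std
                col <- paste0(col, "_std")
              }
              covs <- c(covs, col)
            }
            fit <- fit_poisson_hazard(pm, covariates = covs, subjects = dd,
                                      exposure = exp_col,
                                      exposure_sd = std$sd)
            if (!fit$converged) stop("fit did not converge")
            list(gr = gradient_of_risk(fit, level = level),
                 n = nrow(dd), events = fit$n_events)
          }, error = function(e) e)
          if (inherits(g, "error")) {
            n_failed <- n_failed + 1L
            warning(sprintf("cohort %s skipped for %s/%s [%s]: %s",
                            cname, exposure, outcome, ar$label,
                            conditionMessage(g)), call. = FALSE)
          } else {
            betas <- c(betas, g$gr$beta); ses <- c(ses, g$gr$se)
            labs <- c(labs, cname)
            n_cc <- n_cc + g$n; n_ev <- n_ev + g$events
            per_cohort[[length(per_cohort) + 1L]] <- data.frame(
              exposure = exposure, adjustment = ar$label,
              outcome = outcome, cohort = cname,
              beta = g$gr$beta, se = g$gr$se, n = g$n, events = g$events,
              stringsAsFactors = FALSE)
          }
        }
        if (length(betas)) {
          mm <- pool_fixed_effects(betas, ses, labs, level = level)
          rows[[length(rows) + 1L]] <- data.frame(
            exposure = exposure, adjustment = ar$label, outcome = outcome,
            k = mm$k, n = n_cc, events = n_ev,
            gr = mm$hr, ci_low = mm$ci_low, ci_high = mm$ci_high,
            p = mm$p, q = mm$q, i2 = mm$i2, flagged = n_failed,
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            exposure = exposure, adjustment = ar$label, outcome = outcome,
            k = 0L, n = 0L, events = 0L, gr = NA_real_, ci_low = NA_real_,
            ci_high = NA_real_, p = NA_real_, q = NA_real_, i2 = NA_real_,
            flagged = n_failed, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cohort_estimates") <-
    if (length(per_cohort)) do.call(rbind, per_cohort) else NULL
  attr(out, "level") <- level
  class(out) <- c("gr_grid", "data.frame")
  out
}

#' @export
print.gr_grid <- function(x, ...) {
  exposure_name <- c(csa = "Muscle cross-sectional area",
                     density = "Muscle density")
  for (exposure in unique(x$exposure)) {
    sub <- x[x$exposure == exposure, , drop = FALSE]
    cat(exposure_name[[exposure]], "- gradient of risk (95% CI)\n")
    adj <- unique(sub$adjustment)
    ocs <- unique(sub$outcome)
    m <- matrix("", length(adj), length(ocs),
                dimnames = list(adj, ocs))
    for (i in seq_len(nrow(sub))) {
      m[sub$adjustment[i], sub$outcome[i]] <-
        if (is.na(sub$gr[i])) "--"
        else format_gr(sub$gr[i], sub$ci_low[i], sub$ci_high[i])
    }
    print(as.data.frame(m), right = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Forest plot of pooled gradients of risk
#'
#' @param x a \code{gr_grid} result.
#' @param outcome which outcome column to draw (default \code{"mof"}).
#' @param ... passed to \code{plot.default}.
#' @export
plot.gr_grid <- function(x, outcome = "mof", ...) {
  sub <- x[x$outcome == outcome & !is.na(x$gr), , drop = FALSE]
  if (nrow(sub) == 0L) stop("nothing to plot for outcome ", outcome)
  sub <- sub[rev(seq_len(nrow(sub))), , drop = FALSE]
  ypos <- seq_len(nrow(sub))
  xlim <- range(c(sub$ci_low, sub$ci_high, 1))
  old <- graphics::par(mar = c(4, 16, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(sub$gr, ypos, log = "x", xlim = xlim, pch = 15,
                 yaxt = "n", ylab = "",
                 xlab = "Gradient of risk (HR per SD, 95% CI)",
                 main = paste("Outcome:", outcome), ...)
  graphics::segments(sub$ci_low, ypos, sub$ci_high, ypos)
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::axis(2, at = ypos, las = 1, cex.axis = 0.7,
                 labels = paste(sub$exposure, sub$adjustment, sep = ": "))
  invisible(x)
}
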