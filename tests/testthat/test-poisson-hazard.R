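test_that("within-cohort standardization has the documented closed form", {
  z <- standardize_exposure(c(1, 2, 3), "a")
  expect_equal(z$std, c(-1, 0, 1))
  expect_equal(unname(z$sd), 1)

  # affine transforms of the raw scale leave the standardized vector alone
  set.seed(4)
  x <- rnorm(200, 50, 9)
  g <- rep(c("a", "b"), each = 100)
  expect_equal(standardize_exposure(7.3 * x + 11, g)$std,
               standardize_exposure(x, g)$std, tolerance = 1e-12)

  expect_error(standardize_exposure(c(1, 2, 3, 3), c("a", "a", "b", "b")),
               "cohort\\(s\\): b")
})

test_that("standardization recovers the configured exposure SD", {
  dat <- generate_cohort(mros_cohort_configs()$hk, seed = 37)
  sd_hat <- standardize_exposure(dat$density, dat$cohort)$sd[["hk"]]
  expect_lt(abs(sd_hat - 3.6), 3 * 3.6 / sqrt(2 * nrow(dat)))
})

test_that("intercept-only fit equals log(events / person-years) exactly", {
  # 1662 subjects, total person-time 13541.8 years, 47 hip fractures
  fu <- 13541.8 / 1662
  s <- make_subjects(n = 1662, followup = fu)
  s$fracture_events[1:47] <- sprintf("hip:%.17g", fu)
  pm <- split_followup(s, "hip")
  fit <- fit_poisson_hazard(pm, base_terms = character())
  expect_equal(fit$n_events, 47L)
  expect_equal(fit$person_years, 13541.8, tolerance = 1e-8)
  expect_equal(unname(fit$beta[1]), log(47 / 13541.8), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("the fitter matches an independent IRLS implementation", {
  cfg <- quick_config(n = 800, rate = 0.08, age_coef = 0.05,
                      true_log_hr = c(density = log(0.8), bmi = log(1.1)),
                      seed = 53)
  dat <- generate_cohort(cfg)
  dat$density_std <- standardize_exposure(dat$density, dat$cohort)$std
  pm <- split_followup(dat, "any", covariates = c("density_std", "bmi"))
  fit <- fit_poisson_hazard(pm, covariates = c("density_std", "bmi"))
  ref <- stats::glm(event ~ t_current + age_current + density_std + bmi,
                    family = stats::poisson(),
                    offset = log(delta_t), data = pm)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$cov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  eta_glm <- predict(ref)  # includes the log(delta_t) offset
  expect_equal(fit$loglik,
               sum(pm$event * (eta_glm - log(pm$delta_t)) - exp(eta_glm)),
               tolerance = 1e-6)
})

test_that("score vanishes and information is positive definite at the optimum", {
  cfg <- quick_config(n = 600, rate = 0.1, true_log_hr = c(csa = log(0.9)),
                      seed = 61)
  dat <- generate_cohort(cfg)
  dat$csa_std <- standardize_exposure(dat$csa, dat$cohort)$std
  pm <- split_followup(dat, "any", covariates = "csa_std")
  fit <- fit_poisson_hazard(pm, covariates = "csa_std")
  X <- cbind(1, pm$t_current, pm$age_current, pm$csa_std)
  mu <- exp(drop(X %*% fit$beta)) * pm$delta_t
  score <- drop(crossprod(X, pm$event - mu))
  expect_lt(max(abs(score)), 1e-6 * fit$n_events)
  expect_gt(min(eigen(crossprod(X, X * mu), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  # concavity: the observed information is PSD at arbitrary beta too
  set.seed(8)
  for (i in 1:5) {
    b <- fit$beta + rnorm(4, 0, 0.5)
    w <- exp(drop(X %*% b)) * pm$delta_t
    expect_gte(min(eigen(crossprod(X, X * w), symmetric = TRUE,
                         only.values = TRUE)$values), 0)
  }
})

test_that("a randomly permuted exposure shows no association", {
  cfg <- quick_config(n = 3000, rate = 0.05, seed = 67, fu_mean = 6)
  dat <- generate_cohort(cfg)
  set.seed(99)
  dat$density <- sample(dat$density)
  fit <- fit_cohort_model(dat, model_spec("any", "density"))
  g <- gradient_of_risk(fit)
  expect_lt(abs(g$beta), 3 * g$se)
})

test_that("gradient of risk exponentiates the exposure coefficient", {
  fake <- structure(list(beta = c(`(Intercept)` = -5, x = 0),
                         cov = diag(c(0.04, 0.01)), converged = TRUE,
                         exposure = "x"),
                    class = "poisson_hazard")
  dimnames(fake$cov) <- list(names(fake$beta), names(fake$beta))
  g <- gradient_of_risk(fake)
  expect_equal(g$hr, 1)
  expect_equal(g$ci_low, exp(-0.196), tolerance = 1e-3)
  expect_equal(g$ci_high, exp(0.196), tolerance = 1e-3)
  expect_equal(g$p, 1)

  # presentation format: two decimals, CI in parentheses
  expect_equal(format_gr(0.84, 0.72, 1.0045), "0.84 (0.72, 1.00)")
  fake$beta[["x"]] <- log(0.84)
  fake$cov["x", "x"] <- 0.09^2
  expect_match(format_gr(gradient_of_risk(fake)),
               "^0\\.84 \\(0\\.[0-9]{2}, 1\\.[0-9]{2}\\)$")

  fake$converged <- FALSE
  expect_error(gradient_of_risk(fake), "converge")
})

test_that("the gradient of risk is invariant to raw exposure units", {
  cfg <- quick_config(n = 1000, rate = 0.1, true_log_hr = c(csa = log(0.8)),
                      seed = 71)
  dat <- generate_cohort(cfg)
  g1 <- gradient_of_risk(fit_cohort_model(dat, model_spec("any", "csa")))
  dat2 <- dat
  dat2$csa <- dat2$csa * 100  # cm^2 -> mm^2
  g2 <- gradient_of_risk(fit_cohort_model(dat2, model_spec("any", "csa")))
  expect_equal(g1$hr, g2$hr, tolerance = 1e-10)
  expect_equal(g1$ci_low, g2$ci_low, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected with diagnostics", {
  pm <- split_followup(make_subjects(followup = 2), "any")
  expect_error(fit_poisson_hazard(pm), "no events")

  s <- make_subjects(n = 20, followup = 2,
                     fracture_events = c("hip:1", rep("", 19)))
  pm2 <- split_followup(s, "any")
  pm2$dup <- pm2$t_current  # duplicated column -> rank deficiency
  expect_error(fit_poisson_hazard(pm2, covariates = "dup"),
               "rank deficient")
  pm2$withna <- NA_real_
  expect_error(fit_poisson_hazard(pm2, covariates = "withna"), "missing")
})

test_that("model predictions and residuals are consistent", {
  cfg <- quick_config(n = 500, rate = 0.1, seed = 73)
  dat <- generate_cohort(cfg)
  pm <- split_followup(dat, "any")
  fit <- fit_poisson_hazard(pm)
  mu <- predict(fit, pm, type = "events")
  expect_equal(sum(mu), fit$n_events, tolerance = 1e-6)  # score eq. for intercept
  expect_equal(predict(fit, pm, type = "hazard") * pm$delta_t, mu,
               tolerance = 1e-12)
  r <- residuals(fit, pm)
  expect_equal(sum(r), 0, tolerance = 1e-6)
  expect_equal(logLik(fit)[1], fit$loglik)
  expect_equal(nobs(fit), nrow(pm))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= fit$beta & fit$beta <= ci[, 2]))
})
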