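test_that("follow-up splits into monthly intervals with exact exposure", {
  # one month of follow-up, no events
  pm1 <- split_followup(make_subjects(followup = 1 / 12), "any")
  expect_equal(nrow(pm1), 1L)
  expect_equal(pm1$delta_t, 1 / 12)
  expect_equal(pm1$event, 0L)

  # 5.3 years: 63 full months + one partial month of 0.3 x 12 = 3.6/12
  pm2 <- split_followup(make_subjects(followup = 5.3), "any")
  expect_equal(nrow(pm2), 64L)
  expect_equal(pm2$interval_index, 0:63)
  expect_equal(pm2$delta_t[1:63], rep(1 / 12, 63))
  expect_equal(pm2$delta_t[64], 5.3 - 63 / 12, tolerance = 1e-12)
  expect_equal(sum(pm2$delta_t), 5.3, tolerance = 1e-12)
  expect_equal(pm2$t_current, (0:63) / 12)
  expect_equal(pm2$age_current, 75 + (0:63) / 12)
})

test_that("censoring rules: first qualifying fracture ends risk, death never seen", {
  s <- make_subjects(followup = 10, fracture_events = "hip:2",
                     death_time = 2.5)
  pm <- split_followup(s, "hip")
  expect_equal(nrow(pm), 24L)  # event at a boundary belongs to the earlier interval
  expect_equal(pm$event[24], 1L)
  expect_equal(sum(pm$event), 1L)
  expect_equal(sum(pm$delta_t), 2, tolerance = 1e-12)

  # the same subject under an outcome the fracture does not qualify for is
  # censored by death instead
  s2 <- make_subjects(followup = 10, fracture_events = "fingers:2",
                      death_time = 2.5)
  pm2 <- split_followup(s2, "hip")
  expect_equal(nrow(pm2), 30L)
  expect_equal(sum(pm2$event), 0L)

  # loss to follow-up censors like death
  s3 <- make_subjects(followup = 10, loss_time = 1.25)
  pm3 <- split_followup(s3, "any")
  expect_equal(nrow(pm3), 15L)
  expect_equal(sum(pm3$delta_t), 1.25, tolerance = 1e-12)
})

test_that("non-qualifying earlier fractures do not censor a later outcome", {
  s <- make_subjects(followup = 10, fracture_events = "ribs:1;hip:4")
  pm_hip <- split_followup(s, "hip")
  expect_equal(sum(pm_hip$delta_t), 4, tolerance = 1e-12)
  expect_equal(pm_hip$event[nrow(pm_hip)], 1L)
  pm_ost <- split_followup(s, "osteoporotic")
  expect_equal(sum(pm_ost$delta_t), 1, tolerance = 1e-12)
})

test_that("person-time conservation and outcome nesting hold on simulated data", {
  dat <- generate_cohort(quick_config(n = 1500, rate = 0.12,
                                      death_rate = 0.05, seed = 13))
  risk_time <- function(outcome) {
    pm <- split_followup(dat, outcome)
    out <- numeric(nrow(dat))
    agg <- tapply(pm$delta_t, pm$subject_row, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  }
  t_any <- risk_time("any"); t_hip <- risk_time("hip")
  t_ost <- risk_time("osteoporotic"); t_mof <- risk_time("mof")

  ft <- first_event_time(dat, "any")
  expected <- pmin(ifelse(is.na(ft), Inf, ft),
                   ifelse(is.na(dat$death_time), Inf, dat$death_time),
                   dat$followup)
  expect_equal(t_any, expected, tolerance = 1e-9)
  # narrower outcomes censor no earlier
  expect_true(all(t_ost >= t_any - 1e-12))
  expect_true(all(t_mof >= t_ost - 1e-12))
  expect_true(all(t_hip >= t_mof - 1e-12))

  # structural invariants of the expansion
  pm <- split_followup(dat, "any")
  expect_true(all(pm$delta_t > 0 & pm$delta_t <= 1 / 12 + 1e-12))
  last <- cumsum(rle(pm$subject_row)$lengths)
  expect_true(all(which(pm$event == 1L) %in% last))
  expect_true(all(tapply(pm$event, pm$subject_row, sum) <= 1))
  # intervals are consecutive from 0
  expect_true(all(tapply(pm$interval_index, pm$subject_row,
                         function(i) identical(i, seq_along(i) - 1L))))
})

test_that("duplicated records carry a fracture stratum and a death stratum", {
  s <- make_subjects(followup = 1)
  both <- duplicate_for_competing(s, "any")
  expect_equal(nrow(both), 24L)
  expect_setequal(unique(both$stratum), c("any", "death"))
  expect_equal(sum(both$event), 0L)
  frac <- both[both$stratum == "any", ]
  dth <- both[both$stratum == "death", ]
  expect_equal(frac[setdiff(names(frac), "stratum")],
               dth[setdiff(names(dth), "stratum")],
               ignore_attr = TRUE)

  s2 <- make_subjects(followup = 10, death_time = 0.5)
  b2 <- duplicate_for_competing(s2, "any")
  expect_equal(sum(b2$stratum == "any"), 6L)
  expect_equal(sum(b2$event[b2$stratum == "any"]), 0L)
  d2 <- b2[b2$stratum == "death", ]
  expect_equal(nrow(d2), 6L)
  expect_equal(d2$event[6], 1L)
})

test_that("fracture-stratum person-time equals the directly computed risk time", {
  dat <- generate_cohort(quick_config(n = 400, rate = 0.1, death_rate = 0.08,
                                      seed = 41))
  both <- duplicate_for_competing(dat, "mof")
  frac <- both[both$stratum == "mof", ]
  direct <- split_followup(dat, "mof")
  expect_equal(sum(frac$delta_t), sum(direct$delta_t), tolerance = 1e-9)
  # death-stratum events equal observed deaths
  expect_equal(sum(both$event[both$stratum == "death"]),
               sum(!is.na(dat$death_time)))
})

test_that("cause-specific fits on stacked records recover both hazards", {
  cfg <- quick_config(n = 4000, rate = 0.05, death_rate = 0.04, seed = 19,
                      fu_mean = 6)
  dat <- generate_cohort(cfg)
  both <- duplicate_for_competing(dat, "any")
  fits <- fit_cause_specific(both, base_terms = character())
  # intercept-only cause-specific rates match the configured constants
  for (nm in c("any", "death")) {
    f <- fits[[nm]]
    rate <- if (nm == "any") 0.05 else 0.04
    se <- sqrt(diag(f$cov))[1]
    expect_lt(abs(f$beta[[1]] - log(rate)), 3 * se)
  }
  # and each equals the fit on its own stratum alone
  solo <- fit_poisson_hazard(split_followup(dat, "any"),
                             base_terms = character())
  expect_equal(fits$any$beta, solo$beta, tolerance = 1e-10)
})
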