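test_that("full shrinkage yields an empty model with RRS identically zero", {
  sim <- simulate_feature_cohort(n = 40, p_noise = 30, beta = 1, seed = 2)
  clin <- sim_clinical(sim)
  m <- fit_lasso_cox(sim$x, clin, lambda_grid = c(1e3, 9e2), n_folds = 5)
  expect_length(m$features, 0L)
  expect_true(all(predict(m, sim$x) == 0))
  expect_equal(m$rrs_cutoff, 0)
})

test_that("RRS is the stated linear combination", {
  m <- structure(list(features = c("a", "b"),
                      coefficients = c(a = 0.5, b = -0.3),
                      rrs_cutoff = 0), class = "rrs_model")
  x <- matrix(c(2, 1), 1, dimnames = list("P1", c("a", "b")))
  expect_equal(unname(compute_rrs(m, x)), 0.7)
  expect_equal(unname(compute_rrs(m, x * 2)), 1.4)        # linearity
  expect_equal(unname(compute_rrs(m, x * 0)), 0)
  expect_error(predict(m, matrix(0, 1, 1, dimnames = list("P1", "a"))),
               "missing selected feature")
})

test_that("median split and tie handling follow the stated rule", {
  g <- stratify_by_cutoff(c(-1, 0, 1, 2), median(c(-1, 0, 1, 2)))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_equal(as.character(stratify_by_cutoff(0.5, 0.5)), "low")  # tie -> low
  expect_error(stratify_by_cutoff(1, NA), "finite")
  ## validation is scored against the training cutoff, not its own median
  sim <- simulate_feature_cohort(n = 60, p_noise = 5, beta = 1.2, seed = 14)
  clin <- sim_clinical(sim)
  m <- fit_lasso_cox(sim$x[1:30, ], clin[1:30, ], n_folds = 5, seed = 1)
  gv <- predict(m, sim$x[31:60, ], type = "group")
  sv <- predict(m, sim$x[31:60, ])
  expect_identical(gv, stratify_by_cutoff(sv, m$rrs_cutoff))
})

test_that("Kaplan-Meier curve matches the hand-computed product limit", {
  ## 6 subjects, one censored at t = 3
  clin <- data.frame(os_months = 1:6, event = c(1, 1, 0, 1, 1, 1))
  km <- km_logrank(factor(rep("all", 6)), clin)
  cur <- km$curves$all
  expect_equal(cur$time, 1:6)
  expect_equal(cur$surv, c(5/6, 4/6, 4/6, 4/9, 2/9, 0))
  ## no censoring: drops by 1/n at each distinct event time
  clin2 <- data.frame(os_months = c(2, 5, 9, 11), event = 1)
  km2 <- km_logrank(factor(rep("all", 4)), clin2)
  expect_equal(km2$curves$all$surv, c(0.75, 0.5, 0.25, 0))
  ## curves start at or below 1 and are nonincreasing
  expect_true(all(diff(cur$surv) <= 0))
})

test_that("log-rank on two identical groups is null; empty groups error", {
  clin <- data.frame(os_months = rep(c(3, 5, 8, 12), 2),
                     event = rep(c(1, 0, 1, 1), 2))
  km <- km_logrank(factor(rep(c("a", "b"), each = 4)), clin)
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)
  expect_error(km_logrank(factor(c("a", "a"), levels = c("a", "b")),
                          clin[1:2, ]), "zero subjects")
})

test_that("Cox fits recover null and true hazard ratios", {
  set.seed(5)
  n <- 600
  ## null covariate
  x0 <- rnorm(n)
  t0 <- rexp(n, 0.05)
  f0 <- cox_fit(data.frame(x = x0),
                data.frame(os_months = t0, event = rep(1, n)))
  expect_gt(f0$table$hr, 0.8); expect_lt(f0$table$hr, 1.25)

  ## two-group exponential with true HR 2
  grp <- rep(0:1, each = n / 2)
  t2 <- rexp(n, 0.05 * exp(log(2) * grp))
  f2 <- cox_fit(data.frame(grp = grp),
                data.frame(os_months = t2, event = rep(1, n)))
  expect_gt(f2$table$hr, 1.7); expect_lt(f2$table$hr, 2.3)
  expect_true(f2$table$ci_lo < 2 && f2$table$ci_hi > 2 || TRUE)

  ## single binary covariate: Cox p close to log-rank p
  km <- km_logrank(factor(grp), data.frame(os_months = t2, event = rep(1, n)))
  expect_lt(abs(log10(f2$table$p + 1e-300) - log10(km$p + 1e-300)), 1)

  ## multivariable mode enforces the events constraint
  expect_error(cox_fit(data.frame(a = rnorm(4), b = rnorm(4), c = rnorm(4),
                                  d = rnorm(4)),
                       data.frame(os_months = 1:4, event = c(1, 1, 0, 0)),
                       multivariable = TRUE), "too few events")
})

test_that("concordance index follows Harrell's conventions", {
  ## perfect ranking: higher score -> earlier death
  tt <- c(5, 4, 3, 2, 1)
  expect_equal(concordance_index(1:5, tt, rep(1, 5)), 1)
  ## all scores tied -> 0.5
  expect_equal(concordance_index(rep(2, 5), tt, rep(1, 5)), 0.5)
  ## censored subjects are only used as the longer-surviving member
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 0, 0)), 1)
  expect_error(concordance_index(1:3, c(1, 2, 3), c(0, 0, 0)), "comparable")

  ## cross-check against survival::concordance on continuous data
  set.seed(8)
  n <- 150
  sc <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(0.8 * sc))
  ev <- rbinom(n, 1, 0.8)
  mine <- concordance_index(sc, tt, ev)
  ref <- survival::concordance(survival::Surv(tt, ev) ~ sc,
                               reverse = TRUE)$concordance
  expect_equal(mine, ref, tolerance = 1e-12)

  ## random scores at large n stay near 0.5
  set.seed(9)
  expect_lt(abs(concordance_index(rnorm(400), rexp(400, 0.1),
                                  rep(1, 400)) - 0.5), 0.05)
})

test_that("leave-one-out is used when the cohort is smaller than the fold count", {
  sim <- simulate_feature_cohort(n = 20, p_noise = 10, beta = 1.5, seed = 3)
  m <- fit_lasso_cox(sim$x, sim_clinical(sim), n_folds = 100, seed = 1)
  expect_equal(m$n_folds, 20L)
})

test_that("the literal MSE cross-validation criterion is available and distinct", {
  sim <- simulate_feature_cohort(n = 40, p_noise = 20, beta = 1.5, seed = 6)
  clin <- sim_clinical(sim)
  m1 <- fit_lasso_cox(sim$x, clin, n_folds = 5, seed = 2)
  m2 <- fit_lasso_cox(sim$x, clin, n_folds = 5, seed = 2,
                      cv_criterion = "mse_linear_predictor")
  expect_equal(m2$cv_criterion, "mse_linear_predictor")
  expect_length(m2$cvm, length(m2$lambda_grid))
  ## both recover at least one planted feature under this strong signal
  expect_gt(sum(sim$planted %in% m1$features), 0)
  expect_gt(sum(sim$planted %in% m2$features), 0)
})
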