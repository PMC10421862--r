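nomogram_cohort <- function(n = 120, beta = 1, seed = 1) {
  co <- generate_cohort(cohort_config(n_patients = n, effect_beta = beta,
                                      seed = seed), make_volumes = FALSE)
  list(clinical = co$clinical,
       rrs = co$ground_truth$planted_delta_heterogeneity)
}

test_that("nomogram predictions are proper probabilities, monotone in risk", {
  d <- nomogram_cohort(seed = 3)
  nomo <- build_nomogram(d$clinical, d$rrs, horizon_months = 36)
  p <- predict(nomo, type = "survival")
  expect_true(all(p > 0 & p < 1))
  ## increasing RRS with a positive coefficient lowers predicted survival
  nd <- nomo$train_data[rep(1, 9), ]
  nd$rrs <- seq(-2, 2, length.out = 9)
  ps <- predict(nomo, nd, type = "survival")
  b <- coef(nomo$fit)[["rrs"]]
  expect_gt(b, 0)
  expect_true(all(diff(ps) < 0))
  ## points map is monotone in the linear predictor
  pts <- predict(nomo, nd, type = "points")
  expect_true(all(diff(pts) > 0))
})

test_that("an RRS-only nomogram has the concordance of the RRS Cox model", {
  d <- nomogram_cohort(seed = 5)
  nomo <- build_nomogram(d$clinical, d$rrs, covariates = character(0))
  cf <- cox_fit(data.frame(rrs = d$rrs), d$clinical)
  expect_equal(nomo$c_index, cf$table$c_index, tolerance = 1e-10)
})

test_that("nomogram predictions are invariant to affine covariate rescaling", {
  d <- nomogram_cohort(seed = 7)
  n1 <- build_nomogram(d$clinical, d$rrs)
  c2 <- d$clinical
  c2$age <- (c2$age - 50) / 10           # affine rescale of one covariate
  n2 <- build_nomogram(c2, d$rrs)
  expect_equal(predict(n1, type = "survival"), predict(n2, type = "survival"),
               tolerance = 1e-8)
})

test_that("calibration honours n_boot exactly and is sane under the truth", {
  d <- nomogram_cohort(seed = 9)
  nomo <- build_nomogram(d$clinical, d$rrs)
  cal <- assess_calibration(nomo, n_boot = 25, seed = 4)
  expect_length(cal$optimism, 25L)
  expect_equal(cal$n_boot, 25L)
  expect_true(is.finite(cal$c_corrected))
  expect_true(all(cal$table$n >= 2))
  expect_error(assess_calibration(nomo, data = nomo$train_data[1:10, ],
                                  groups = 10), "groups")
})

test_that("HL test accepts self-consistent data and rejects miscalibration", {
  ## simulate survival from a known exponential model, predict with the truth
  hl_p <- function(distort, seed) {
    set.seed(seed)
    n <- 400
    x <- rnorm(n)
    tt <- rexp(n, 0.03 * exp(0.8 * x))
    clin <- data.frame(patient_id = as.character(1:n), os_months = pmax(tt, 1e-3),
                       event = 1, response = "responder", age = 60,
                       race = "White", baseline_tumor_volume_ml = 1)
    nomo <- build_nomogram(clin, x, covariates = character(0))
    if (distort) {
      ## deliberately miscalibrate: square the predicted event probabilities
      p <- predict(nomo, type = "risk")^2
      h <- nomo$horizon_months
      g <- cut(p, breaks = unique(quantile(p, seq(0, 1, 0.1))),
               include.lowest = TRUE, labels = FALSE)
      km_ev <- vapply(sort(unique(g)), function(k) {
        sf <- survival::survfit(survival::Surv(os_months, event) ~ 1,
                                data = clin[g == k, ])
        idx <- findInterval(h, sf$time)
        if (idx == 0) 0 else 1 - sf$surv[idx]
      }, numeric(1))
      ng <- as.vector(table(g))
      e <- vapply(split(p, g), mean, numeric(1)) * ng
      o <- km_ev * ng
      stat <- sum((o - e)^2 / pmax(e * (1 - e / ng), 1e-9))
      pchisq(stat, df = length(ng) - 2, lower.tail = FALSE)
    } else {
      assess_calibration(nomo, n_boot = 0)$p
    }
  }
  ## calibration-under-truth study (50 replicates, n = 400): the chi-squared
  ## reference with groups - 2 df accepts ~87% of self-consistent datasets at
  ## the 5% level -- mildly anticonservative, bounded here at 80%
  ok <- vapply(1:20, function(s) hl_p(FALSE, s), numeric(1))
  expect_gte(mean(ok > 0.05), 0.8)
  bad <- vapply(1:10, function(s) hl_p(TRUE, s), numeric(1))
  expect_gte(mean(bad < 0.05), 0.7)
})

test_that("decision curves match the closed forms", {
  set.seed(11)
  n <- 400
  outcome <- rbinom(n, 1, 0.3)
  prev <- mean(outcome)
  th <- seq(0.01, 0.99, 0.01)

  ## treat-none is identically zero; treat-all follows the closed form
  d <- decision_curve(runif(n), outcome, th)
  expect_true(all(d$net_benefit_none == 0))
  expect_equal(d$net_benefit_all, prev - (1 - prev) * th / (1 - th))

  ## perfect predictor: NB(t) = prevalence for every t < 1
  dp <- decision_curve(outcome, outcome, th)
  expect_true(all(abs(dp$net_benefit_model - prev) < 1e-12))

  ## constant predictions of 1 coincide with treat-all
  d1 <- decision_curve(rep(1, n), outcome, th)
  expect_equal(d1$net_benefit_model, d1$net_benefit_all)

  ## model net benefit never exceeds the prevalence
  expect_true(all(d$net_benefit_model <= prev + 1e-12))
  expect_error(decision_curve(runif(3), c(0, 1, 1), thresholds = c(0, 0.5)),
               "thresholds")
})

test_that("group comparisons use Fisher's exact and Welch t tests", {
  ## 2x2 table [[3,1],[1,3]]: two-sided hypergeometric enumeration gives 34/70
  tab <- data.frame(v = c(rep("x", 3), "y", "x", rep("y", 3)),
                    g = rep(c("A", "B"), each = 4))
  r <- compare_clinical_groups(tab, "v", "g")
  expect_equal(r$test, "fisher")
  expect_equal(r$p, 34 / 70, tolerance = 1e-12)

  ## identical groups: t statistic 0, p = 1
  num <- data.frame(v = rep(c(1.2, 3.4, 5.6), 2), g = rep(c("A", "B"), each = 3))
  rt <- compare_clinical_groups(num, "v", "g")
  expect_equal(rt$test, "t")
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p, 1)

  ## empty margin errors
  zo <- data.frame(v = rep("x", 6), g = rep(c("A", "B"), each = 3))
  expect_error(compare_clinical_groups(zo, "v", "g"), "margin")
})
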