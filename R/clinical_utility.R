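#' Build a clinical + radiomic nomogram for horizon survival
#'
#' Fits a multivariable Cox model over the radiomic risk score and clinical
#' covariates (age, race, baseline tumor volume), derives the classical
#' point scale -- each covariate's points are proportional to its coefficient
#' times its observed range, scaled so the widest contribution spans 100
#' points -- and maps total points to the predicted probability of surviving
#' to the horizon through the baseline survival estimate.
#'
#' @param clinical clinical table (needs `os_months`, `event`, `age`, `race`,
#'   `baseline_tumor_volume_ml`).
#' @param rrs numeric radiomic risk scores, one per clinical row.
#' @param horizon_months prediction horizon (default 36 = 3 years).
#' @param covariates which clinical columns to include beside the RRS.
#' @return Object of class `nomogram_model`: the Cox `fit`, the per-covariate
#'   point scale, the total-points-to-survival map parameters, `c_index`,
#'   and the training data (kept for calibration bootstraps).
#' @export
build_nomogram <- function(clinical, rrs, horizon_months = 36,
                           covariates = c("age", "race",
                                          "baseline_tumor_volume_ml")) {
  df <- data.frame(.time = clinical$os_months, .event = clinical$event,
                   rrs = rrs, stringsAsFactors = FALSE)
  for (v in covariates) {
    col <- clinical[[v]]
    df[[v]] <- if (is.character(col)) factor(col) else col
  }
  vars <- c("rrs", covariates)
  f <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                               paste(vars, collapse = " + ")))
  fit <- survival::coxph(f, data = df, ties = "efron", x = TRUE,
                         model = TRUE)
  if (any(!is.finite(stats::coef(fit)))) stop("Cox model did not converge")

  ## per-column (factor levels kept separate) linear contributions beta * x
  X <- fit$x
  beta <- stats::coef(fit)
  contrib_term <- sweep(X, 2, beta, "*")
  terms_lab <- colnames(X)
  lo <- apply(contrib_term, 2, min)
  hi <- apply(contrib_term, 2, max)
  R <- max(hi - lo)
  if (R <= 0) R <- 1

  lp <- drop(X %*% beta)          # centred internally by coxph via means
  cidx <- summary(fit)$concordance[["C"]]

  structure(list(
    fit = fit, horizon_months = horizon_months, covariates = covariates,
    point_scale = data.frame(term = terms_lab, beta_range = hi - lo,
                             min_contrib = lo,
                             points_per_unit_lp = 100 / R,
                             row.names = NULL),
    lp_offset = sum(lo), lp_range = R,
    c_index = cidx, train_data = df),
    class = "nomogram_model")
}

#' @export
print.nomogram_model <- function(x, ...) {
  cat(sprintf("<nomogram_model> %d-month survival; C-index = %.3f\n",
              x$horizon_months, x$c_index))
  cat("  terms:", paste(x$point_scale$term, collapse = ", "), "\n")
  invisible(x)
}

#' Nomogram predictions
#'
#' @param object a `nomogram_model`.
#' @param newdata data.frame with the model covariates plus `rrs`; defaults to
#'   the training data.
#' @param type `"survival"` (probability of surviving to the horizon),
#'   `"risk"` (1 - survival), `"lp"` (linear predictor) or `"points"` (total
#'   nomogram points).
#' @param ... unused.
#' @export
predict.nomogram_model <- function(object, newdata = NULL,
                                   type = c("survival", "risk", "lp", "points"),
                                   ...) {
  type <- match.arg(type)
  nd <- newdata %||% object$train_data
  lp <- stats::predict(object$fit, newdata = nd, type = "lp")
  if (type == "lp") return(lp)
  if (type == "points") {
    ## shift so the lowest observed per-term contribution maps to 0 points
    return((lp + sum(object$fit$means * stats::coef(object$fit)) -
              object$lp_offset) * 100 / object$lp_range)
  }
  sf <- survival::survfit(object$fit, newdata = nd)
  idx <- findInterval(object$horizon_months, sf$time)
  s <- if (idx == 0) rep(1, length(lp)) else {
    sm <- if (is.matrix(sf$surv)) sf$surv[idx, ] else sf$surv[idx]
    as.numeric(sm)
  }
  s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  if (type == "survival") s else 1 - s
}

#' Calibration of horizon survival predictions
#'
#' Groups patients into deciles of predicted horizon event probability,
#' compares each group's mean prediction with the Kaplan-Meier-observed event
#' proportion at the horizon (censoring-aware), computes a Hosmer-Lemeshow
#' chi-squared statistic with `groups - 2` degrees of freedom, and quantifies
#' optimism of the model concordance by refitting on bootstrap resamples.
#' Deciles too small to evaluate are merged with their neighbour.
#'
#' @param model a [build_nomogram()] result.
#' @param data data.frame like the nomogram training data (`.time`, `.event`,
#'   covariates, `rrs`); defaults to the training data.
#' @param n_boot bootstrap resamples for the optimism correction (0 skips it).
#' @param groups number of risk groups (default 10).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `calibration_result`: per-group `table`
#'   (`n`, `predicted`, `observed`), `hl_stat`, `df`, `p`,
#'   `c_apparent`, `c_corrected`, and the per-resample `optimism` trace.
#' @export
assess_calibration <- function(model, data = NULL, n_boot = 500, groups = 10,
                               seed = 1L) {
  data <- data %||% model$train_data
  if (nrow(data) < groups * 2) stop("need at least groups * 2 subjects")
  p_event <- predict(model, data, type = "risk")
  h <- model$horizon_months

  ## decile grouping on predicted risk; merge groups with < 2 subjects
  br <- unique(stats::quantile(p_event, probs = seq(0, 1, length.out = groups + 1)))
  g <- cut(p_event, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab_n <- table(g)
  while (any(tab_n < 2) && length(tab_n) > 2) {
    small <- as.integer(names(tab_n)[which.min(tab_n)])
    neighbour <- if (small == max(g)) small - 1L else small + 1L
    g[g == small] <- neighbour
    g <- as.integer(factor(g))
    tab_n <- table(g)
  }

  km_event_at <- function(time, event) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    idx <- findInterval(h, sf$time)
    if (idx == 0) 0 else 1 - sf$surv[idx]
  }
  grp <- sort(unique(g))
  tab <- do.call(rbind, lapply(grp, function(k) {
    i <- g == k
    data.frame(group = k, n = sum(i),
               predicted = mean(p_event[i]),
               observed = km_event_at(data$.time[i], data$.event[i]))
  }))
  ## Hosmer-Lemeshow on expected vs KM-observed event counts
  e <- tab$predicted * tab$n
  o <- tab$observed * tab$n
  denom <- pmax(e * (1 - e / tab$n), 1e-9)
  hl <- sum((o - e)^2 / denom)
  df <- max(1L, nrow(tab) - 2L)
  p <- stats::pchisq(hl, df = df, lower.tail = FALSE)

  optimism <- numeric(0)
  c_app <- model$c_index
  c_corr <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    f <- stats::formula(model$fit)
    full <- model$train_data
    optimism <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(full), replace = TRUE)
      bfit <- tryCatch(
        survival::coxph(f, data = full[idx, , drop = FALSE], ties = "efron"),
        error = function(e) NULL)
      if (is.null(bfit)) return(NA_real_)
      c_boot <- summary(bfit)$concordance[["C"]]
      lp_orig <- stats::predict(bfit, newdata = full, type = "lp")
      c_orig <- concordance_index(lp_orig, full$.time, full$.event)
      c_boot - c_orig
    }, numeric(1))
    c_corr <- c_app - mean(optimism, na.rm = TRUE)
  }
  structure(list(table = tab, hl_stat = hl, df = df, p = p,
                 c_apparent = c_app, c_corrected = c_corr,
                 optimism = optimism, n_boot = n_boot),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> HL chisq = %.3g on %d df, p = %.3g\n",
              x$hl_stat, x$df, x$p))
  if (x$n_boot > 0)
    cat(sprintf("  C-index: apparent %.3f, optimism-corrected %.3f (%d resamples)\n",
                x$c_apparent, x$c_corrected, x$n_boot))
  invisible(x)
}

#' @export
plot.calibration_result <- function(x, ...) {
  graphics::plot(x$table$predicted, x$table$observed, pch = 16,
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Predicted event probability",
                 ylab = "Observed (Kaplan-Meier) event probability", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Decision curve analysis
#'
#' Net benefit of acting on model predictions across threshold probabilities:
#' `NB(t) = TP(t)/n - FP(t)/n * t/(1-t)` where a patient is treated when the
#' predicted probability is at least `t`. Reference strategies: treat-all
#' (`pi - (1-pi) t/(1-t)` at prevalence `pi`) and treat-none (identically 0).
#'
#' @param predictions event probabilities in `[0, 1]`.
#' @param outcomes 0/1 observed events.
#' @param thresholds threshold grid in (0, 1); default 0.01 to 0.99 step 0.01.
#' @return data.frame of class `dca_curves`: `threshold`, `net_benefit_model`,
#'   `net_benefit_all`, `net_benefit_none`.
#' @export
decision_curve <- function(predictions, outcomes,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(length(predictions) == length(outcomes),
            all(outcomes %in% c(0, 1)),
            all(thresholds > 0 & thresholds < 1))
  n <- length(outcomes)
  prev <- mean(outcomes)
  nb <- vapply(thresholds, function(t) {
    treat <- predictions >= t
    tp <- sum(treat & outcomes == 1)
    fp <- sum(treat & outcomes == 0)
    tp / n - fp / n * t / (1 - t)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  structure(data.frame(threshold = thresholds, net_benefit_model = nb,
                       net_benefit_all = nb_all, net_benefit_none = 0),
            class = c("dca_curves", "data.frame"), prevalence = prev)
}

#' @export
plot.dca_curves <- function(x, ...) {
  graphics::plot(x$threshold, x$net_benefit_model, type = "l", lwd = 2,
                 ylim = range(c(x$net_benefit_model, x$net_benefit_all, 0)),
                 xlab = "Threshold probability", ylab = "Net benefit", ...)
  graphics::lines(x$threshold, x$net_benefit_all, col = "grey40")
  graphics::abline(h = 0, lty = 2)
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   col = c("black", "grey40", "black"),
                   lty = c(1, 1, 2), lwd = c(2, 1, 1))
  invisible(x)
}

#' Compare a clinical variable between two groups
#'
#' Welch two-sided t-test for continuous variables, Fisher's exact test for
#' categorical ones (on the contingency table with `grouping`).
#'
#' @param data data.frame.
#' @param variable column to compare.
#' @param grouping column defining the two groups.
#' @return list: `test` ("t" or "fisher"), `statistic` (t statistic or odds
#'   ratio), `p`.
#' @export
compare_clinical_groups <- function(data, variable, grouping) {
  v <- data[[variable]]
  gl <- as.factor(data[[grouping]])
  if (nlevels(gl) != 2L) stop("grouping must have exactly two levels")
  if (is.numeric(v)) {
    tt <- stats::t.test(v ~ gl, alternative = "two.sided")
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    tab <- table(as.factor(v), gl)
    if (nrow(tab) < 2L || ncol(tab) < 2L ||
        any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("contingency table has an empty margin")
    ft <- stats::fisher.test(tab)
    list(test = "fisher",
         statistic = unname(ft$estimate %||% NA_real_), p = ft$p.value)
  }
}
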