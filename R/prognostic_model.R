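#' Fit a LASSO-Cox radiomic risk score
#'
#' Selects prognostic delta features by an L1-penalized Cox partial-likelihood
#' fit (coordinate descent via glmnet) with the penalty chosen on a grid of
#' 100 log-spaced values by cross-validation; the number of folds is
#' `min(n_folds, n)`, i.e. leave-one-out when the cohort is smaller than the
#' requested fold count. The radiomic risk score (RRS) of a patient is the
#' linear combination of the selected features weighted by their coefficients,
#' and the risk-group cutoff is the median training RRS.
#'
#' The default cross-validation criterion is the Cox partial-likelihood
#' deviance; `cv_criterion = "mse_linear_predictor"` instead minimizes the
#' held-out mean squared error between the linear predictor and a centred
#' `-log(time)` surrogate (a literal mean-squared-error reading, kept for
#' sensitivity analyses).
#'
#' @param deltas delta feature table ([build_delta_table()]) or a numeric
#'   matrix with rownames/`patient_id` column.
#' @param clinical clinical table with `patient_id`, `os_months`, `event`.
#' @param lambda_grid optional penalty grid (default: 100 log-spaced values
#'   down to 0.01 of the largest useful penalty; deeper paths are numerically
#'   unstable for the saturated Cox fits that arise when p >> events).
#' @param n_folds requested CV folds (default 100; capped at n).
#' @param seed RNG seed for fold assignment.
#' @param cv_criterion `"deviance"` or `"mse_linear_predictor"`.
#' @return Object of class `rrs_model`: selected `features` and
#'   `coefficients`, `lambda`, `lambda_grid`, `cvm` (criterion trace),
#'   `rrs_cutoff`, training scores and concordance, and the normalization
#'   reference when the delta table carries one.
#' @export
fit_lasso_cox <- function(deltas, clinical, lambda_grid = NULL, n_folds = 100,
                          seed = 1L,
                          cv_criterion = c("deviance", "mse_linear_predictor")) {
  cv_criterion <- match.arg(cv_criterion)
  xm <- as_delta_matrix(deltas)
  clinical <- align_clinical(clinical, rownames(xm))
  n <- nrow(xm)
  if (n < 10L) stop("need at least 10 patients")
  if (sum(clinical$event) < 1L) stop("no events in the cohort")
  keep <- apply(xm, 2, function(v) all(is.finite(v)) && stats::sd(v) > 0)
  if (!any(keep)) stop("all features are constant or missing")
  xm <- xm[, keep, drop = FALSE]
  y <- survival::Surv(clinical$os_months, clinical$event)

  nfolds <- min(n_folds, n)
  set.seed(seed)
  foldid <- if (nfolds == n) seq_len(n) else sample(rep(seq_len(nfolds), length.out = n))

  if (cv_criterion == "deviance") {
    cv <- glmnet::cv.glmnet(xm, y, family = "cox", type.measure = "deviance",
                            foldid = foldid, lambda = lambda_grid,
                            nlambda = 100, lambda.min.ratio = 0.01)
    lambda <- cv$lambda.min
    grid <- cv$lambda
    cvm <- cv$cvm
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(xm, y, family = "cox", lambda = lambda_grid,
                          nlambda = 100, lambda.min.ratio = 0.01)
    grid <- fit$lambda
    target <- as.numeric(scale(-log(clinical$os_months)))
    errs <- matrix(NA_real_, nfolds, length(grid))
    for (f in seq_len(nfolds)) {
      tr <- foldid != f
      ff <- glmnet::glmnet(xm[tr, , drop = FALSE], y[tr, ], family = "cox",
                           lambda = grid)
      lp <- stats::predict(ff, xm[!tr, , drop = FALSE], s = grid)
      errs[f, ] <- colMeans((lp - target[!tr])^2)
    }
    cvm <- colMeans(errs, na.rm = TRUE)
    lambda <- grid[which.min(cvm)]
  }

  beta <- stats::coef(fit, s = lambda)
  sel <- which(as.numeric(beta) != 0)
  features <- rownames(beta)[sel]
  coefs <- stats::setNames(as.numeric(beta)[sel], features)
  scores <- if (length(sel)) drop(xm[, features, drop = FALSE] %*% coefs)
            else rep(0, n)
  names(scores) <- rownames(xm)
  cutoff <- stats::median(scores)

  structure(list(
    features = features, coefficients = coefs, lambda = lambda,
    lambda_grid = grid, cvm = cvm, cv_criterion = cv_criterion,
    n_folds = nfolds, rrs_cutoff = cutoff, seed = seed,
    train_scores = scores,
    train_c_index = concordance_index(scores, clinical$os_months, clinical$event),
    n = n, n_events = sum(clinical$event),
    normalization = attr(deltas, "normalization")),
    class = "rrs_model")
}

#' @rdname fit_lasso_cox
#' @export
fit_rrs <- fit_lasso_cox

as_delta_matrix <- function(deltas) {
  if (is.matrix(deltas)) {
    if (is.null(rownames(deltas))) rownames(deltas) <- as.character(seq_len(nrow(deltas)))
    return(deltas)
  }
  stopifnot(is.data.frame(deltas), "patient_id" %in% names(deltas))
  xm <- as.matrix(deltas[, setdiff(names(deltas), "patient_id"), drop = FALSE])
  rownames(xm) <- deltas$patient_id
  xm
}

align_clinical <- function(clinical, ids) {
  if (!all(ids %in% clinical$patient_id))
    stop("clinical table missing patients: ",
         paste(utils::head(setdiff(ids, clinical$patient_id), 3), collapse = ", "))
  clinical[match(ids, clinical$patient_id), , drop = FALSE]
}

#' @export
print.rrs_model <- function(x, ...) {
  cat(sprintf("<rrs_model> %d selected feature(s) at lambda = %.4g (%s CV, %d folds)\n",
              length(x$features), x$lambda, x$cv_criterion, x$n_folds))
  cat(sprintf("  training: n = %d, events = %d, C-index = %.3f, median RRS cutoff = %.4g\n",
              x$n, x$n_events, x$train_c_index, x$rrs_cutoff))
  invisible(x)
}

#' @export
summary.rrs_model <- function(object, ...) {
  cat("Radiomic risk score (LASSO-Cox)\n")
  print(object)
  if (length(object$coefficients)) {
    cat("\nCoefficients:\n")
    print(round(object$coefficients, 5))
  } else cat("\nFull shrinkage: no features selected; RRS is identically 0.\n")
  invisible(object)
}

#' @export
coef.rrs_model <- function(object, ...) object$coefficients

#' Radiomic risk scores and risk groups for new data
#'
#' @param object an `rrs_model`.
#' @param newdata delta table or matrix containing the selected features.
#' @param type `"score"` (linear combination) or `"group"` (high/low by the
#'   training median cutoff; ties go to low risk).
#' @param ... unused.
#' @export
predict.rrs_model <- function(object, newdata,
                              type = c("score", "group"), ...) {
  type <- match.arg(type)
  xm <- as_delta_matrix(newdata)
  if (length(object$features)) {
    miss <- setdiff(object$features, colnames(xm))
    if (length(miss)) stop("missing selected feature(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    s <- drop(xm[, object$features, drop = FALSE] %*% object$coefficients)
  } else s <- rep(0, nrow(xm))
  names(s) <- rownames(xm)
  if (type == "score") s else stratify_by_cutoff(s, object$rrs_cutoff)
}

#' @rdname predict.rrs_model
#' @param deltas delta table or matrix.
#' @export
compute_rrs <- function(object, deltas) predict(object, deltas, type = "score")

#' @export
plot.rrs_model <- function(x, ...) {
  graphics::plot(log(x$lambda_grid), x$cvm, type = "b", pch = 16, cex = 0.6,
                 xlab = "log(lambda)",
                 ylab = paste0("CV criterion (", x$cv_criterion, ")"), ...)
  graphics::abline(v = log(x$lambda), lty = 2)
  invisible(x)
}

#' Split scores into high/low risk groups at a cutoff
#'
#' High risk iff score strictly exceeds the cutoff; ties go to low risk.
#' Validation cohorts are always scored against the training cutoff.
#'
#' @param scores numeric risk scores.
#' @param cutoff finite cutoff (training median RRS).
#' @return Factor with levels `low`, `high`.
#' @export
stratify_by_cutoff <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' @param groups factor of group labels (each level must be nonempty).
#' @param clinical clinical table (or any data.frame with `os_months`,
#'   `event`) in the same order as `groups`.
#' @return Object of class `km_result`: per-group step curves (`time`,
#'   `surv`), per-group median survival (NA when the curve never crosses 0.5),
#'   log-rank `chisq` and `p`.
#' @export
km_logrank <- function(groups, clinical) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0L)) stop("a group with zero subjects")
  df <- data.frame(time = clinical$os_months, event = clinical$event,
                   group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit)$table
  med <- if (is.matrix(sm)) sm[, "median"] else sm[["median"]]
  names(med) <- sub("^group=", "", names(med) %||% levels(groups)[1])
  curves <- list()
  strata <- rep(names(fit$strata) %||% levels(groups)[1],
                fit$strata %||% length(fit$time))
  for (g in unique(strata)) {
    i <- strata == g
    curves[[sub("^group=", "", g)]] <-
      data.frame(time = fit$time[i], surv = fit$surv[i])
  }
  if (nlevels(groups) > 1) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    chisq <- sd_$chisq
    p <- stats::pchisq(chisq, df = nlevels(groups) - 1L, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; p <- NA_real_
  }
  structure(list(curves = curves, median_survival = med, chisq = chisq, p = p,
                 fit = fit),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result>\n  median survival:",
      paste(sprintf("%s = %.3g", names(x$curves), x$median_survival), collapse = ", "),
      sprintf("\n  log-rank chisq = %.3g, p = %.3g\n", x$chisq, x$p))
  invisible(x)
}

#' @export
plot.km_result <- function(x, col = seq_along(x$curves), ...) {
  graphics::plot(x$fit, col = col, xlab = "Months", ylab = "Survival probability", ...)
  graphics::legend("topright", legend = names(x$curves), col = col, lty = 1)
  invisible(x)
}

#' Cox proportional-hazards fits with hazard ratios and concordance
#'
#' Univariable mode fits one Cox model per covariate; multivariable mode fits
#' a single joint model (requires events >= covariates + 1). Efron tie
#' handling, Wald confidence intervals and p-values, Harrell concordance of
#' each model's linear predictor.
#'
#' @param covariates data.frame of covariates (numeric or factor).
#' @param clinical table with `os_months`, `event` (same row order).
#' @param multivariable fit one joint model instead of per-covariate models.
#' @return Object of class `survival_fit` with a per-covariate `table`
#'   (`hr`, `ci_lo`, `ci_hi`, `p`, `c_index`) and the joint `c_index` for
#'   multivariable fits.
#' @export
cox_fit <- function(covariates, clinical, multivariable = FALSE) {
  covariates <- as.data.frame(covariates)
  df <- cbind(data.frame(.time = clinical$os_months, .event = clinical$event),
              covariates)
  one_fit <- function(vars) {
    f <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", vars), collapse = " + ")))
    fit <- survival::coxph(f, data = df, ties = "efron")
    s <- summary(fit)
    data.frame(covariate = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               ci_lo = s$conf.int[, "lower .95"],
               ci_hi = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               c_index = s$concordance[["C"]],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (multivariable) {
    k <- sum(vapply(covariates, function(v)
      if (is.numeric(v)) 1L else nlevels(as.factor(v)) - 1L, integer(1)))
    if (sum(clinical$event) < k + 1L)
      stop("too few events for a multivariable fit (need >= covariates + 1)")
    tab <- one_fit(names(covariates))
    cidx <- tab$c_index[1]
  } else {
    tab <- do.call(rbind, lapply(names(covariates), one_fit))
    cidx <- NA_real_
  }
  structure(list(table = tab, c_index = cidx, multivariable = multivariable),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> %s\n",
              if (x$multivariable) sprintf("multivariable (C-index = %.3f)", x$c_index)
              else "univariable (per-covariate models)"))
  print(transform(x$table, hr = round(hr, 3), ci_lo = round(ci_lo, 3),
                  ci_hi = round(ci_hi, 3), p = signif(p, 3),
                  c_index = round(c_index, 3)))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Pair-counting implementation: a pair is usable when the shorter observed
#' time is an event (or times are tied and exactly one is an event); it is
#' concordant when the earlier-failing patient has the higher score, and tied
#' scores credit 0.5.
#'
#' @param scores risk scores (higher = higher risk).
#' @param time,event survival times and 0/1 event indicators.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  num <- 0; den <- 0
  for (i in which(event == 1)) {
    comp <- time > time[i] | (time == time[i] & event == 0)
    comp[i] <- FALSE
    if (!any(comp)) next
    den <- den + sum(comp)
    num <- num + sum(scores[i] > scores[comp]) + 0.5 * sum(scores[i] == scores[comp])
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}
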