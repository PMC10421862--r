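## Linear discriminant response classifier over the selected delta features.

#' Mann-Whitney AUC
#'
#' Rank-based area under the ROC curve of `scores` for the positive class;
#' tied scores credit 0.5.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels two-class labels; `positive` names the positive class
#'   (default: last factor level).
#' @param positive positive class label.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  positive <- positive %||% levels(labels)[nlevels(labels)]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a pooled-covariance linear discriminant classifier
#'
#' Classic two-class LDA assuming identical class covariances: the
#' discriminant direction is `solve(S, mu_pos - mu_neg)` for the pooled
#' within-class covariance `S`. When `S` is singular or badly conditioned
#' (p >= n, duplicated columns), a ridge shrinkage toward the scaled identity
#' is applied with the smallest shrinkage weight that makes the system well
#' conditioned. The operating threshold is fixed on the training scores by
#' the Youden index.
#'
#' @param x numeric feature matrix (rows = subjects).
#' @param y two-class labels; the last factor level is the positive class
#'   unless `positive` is given.
#' @param positive positive class label.
#' @param shrinkage optional fixed shrinkage weight in `[0, 1]`; chosen
#'   automatically when `NULL`.
#' @return Object of class `lda_classifier`: weights `w`, class means,
#'   `threshold` (Youden, training), `train_auc`, `shrinkage`.
#' @export
train_lda <- function(x, y, positive = NULL, shrinkage = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("single-class input: need exactly two classes")
  positive <- positive %||% levels(y)[2]
  neg <- setdiff(levels(y), positive)
  x1 <- x[y == positive, , drop = FALSE]
  x0 <- x[y == neg, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  S <- (crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x0, 2, mu0))) /
    max(1, n1 + n0 - 2)
  tr_scale <- mean(diag(S))
  if (tr_scale <= 0) tr_scale <- 1
  gammas <- if (is.null(shrinkage)) c(0, 10^seq(-4, 0, by = 0.5)) else shrinkage
  w <- NULL; used_gamma <- NA_real_
  for (g in gammas) {
    Sg <- (1 - g) * S + g * tr_scale * diag(ncol(S))
    w_try <- tryCatch({
      if (rcond(Sg) < 1e-10) NULL else solve(Sg, mu1 - mu0)
    }, error = function(e) NULL)
    if (!is.null(w_try)) { w <- w_try; used_gamma <- g; break }
  }
  if (is.null(w)) stop("covariance irreparably singular")
  scores <- drop(x %*% w)
  thr <- youden_threshold(scores, y == positive)
  structure(list(w = w, mu_pos = mu1, mu_neg = mu0, classes = levels(y),
                 positive = positive, shrinkage = used_gamma,
                 threshold = thr,
                 train_auc = auc_mw(scores, y, positive = positive)),
            class = "lda_classifier")
}

youden_threshold <- function(scores, pos) {
  u <- sort(unique(scores))
  if (length(u) < 2L) return(NA_real_)  # degenerate: constant scores
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(t) {
    mean(scores[pos] > t) + mean(scores[!pos] <= t) - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' @export
print.lda_classifier <- function(x, ...) {
  cat(sprintf("<lda_classifier> %d features, positive class '%s', training AUC = %.3f\n",
              length(x$w), x$positive, x$train_auc))
  if (x$shrinkage > 0)
    cat(sprintf("  covariance shrinkage gamma = %.4g\n", x$shrinkage))
  invisible(x)
}

#' @export
predict.lda_classifier <- function(object, newdata,
                                   type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- drop(as.matrix(newdata) %*% object$w)
  if (type == "score") return(s)
  neg <- setdiff(object$classes, object$positive)
  if (!is.finite(object$threshold)) {
    warning("degenerate threshold (constant training scores); predicting negative class")
    return(factor(rep(neg, length(s)), levels = object$classes))
  }
  factor(ifelse(s > object$threshold, object$positive, neg),
         levels = object$classes)
}

#' Repeated stratified cross-validated AUC
#'
#' Runs `iterations` independent stratified `folds`-fold partitions; each
#' iteration's AUC is the mean held-out AUC over its folds. Reports the mean
#' AUC, a percentile 95% interval over iterations, and the full per-iteration
#' trace. Deterministic under `seed`.
#'
#' @inheritParams train_lda
#' @param folds folds per iteration (default 3, stratified by class).
#' @param iterations number of repeated partitions (default 100).
#' @param seed RNG seed.
#' @return list: `mean_auc`, `ci` (2.5/97.5 percentiles), `trace`
#'   (length `iterations`).
#' @export
cv_auc <- function(x, y, folds = 3, iterations = 100, seed = 1L,
                   positive = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("need exactly two classes")
  if (min(table(y)) < folds)
    stop("class too small to stratify into ", folds, " folds")
  positive <- positive %||% levels(y)[2]
  set.seed(seed)
  trace <- vapply(seq_len(iterations), function(it) {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      fold[i] <- sample(rep(seq_len(folds), length.out = length(i)))
    }
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- train_lda(x[tr, , drop = FALSE], y[tr], positive = positive)
      auc_mw(predict(m, x[!tr, , drop = FALSE]), y[!tr], positive = positive)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  list(mean_auc = mean(trace),
       ci = stats::quantile(trace, c(0.025, 0.975), names = FALSE),
       trace = trace, folds = folds, iterations = iterations)
}

#' Evaluate a trained classifier on a held-out cohort
#'
#' AUC with a DeLong 95% confidence interval, plus accuracy, sensitivity and
#' specificity at the operating threshold frozen from training (never
#' recomputed on the holdout). A single-class holdout yields a missing AUC.
#'
#' @param model a [train_lda()] classifier.
#' @param x,y holdout features and labels.
#' @return Object of class `classifier_report`: `auc`, `auc_ci`, `accuracy`,
#'   `sensitivity`, `specificity`, `threshold`, `degenerate` flag.
#' @export
evaluate_holdout <- function(model, x, y) {
  y <- factor(y, levels = model$classes)
  s <- predict(model, x)
  pos <- y == model$positive
  single_class <- !any(pos) || all(pos)
  auc <- if (single_class) NA_real_ else auc_mw(s, y, positive = model$positive)
  auc_ci <- c(NA_real_, NA_real_)
  if (!single_class && length(unique(s)) > 1 &&
      requireNamespace("pROC", quietly = TRUE)) {
    ci <- tryCatch(
      suppressMessages(pROC::ci.auc(pROC::roc(
        response = pos, predictor = s, quiet = TRUE, direction = "<"),
        method = "delong")),
      error = function(e) NULL)
    if (!is.null(ci)) auc_ci <- as.numeric(ci)[c(1, 3)]
  }
  degenerate <- !is.finite(model$threshold)
  thr <- if (degenerate) stats::median(s) else model$threshold
  pred_pos <- s > thr
  ## ROC coordinates over all score cutpoints (for export/plotting)
  cuts <- c(-Inf, sort(unique(s)))
  roc <- data.frame(
    threshold = cuts,
    sensitivity = vapply(cuts, function(t) mean(s[pos] > t), numeric(1)),
    specificity = vapply(cuts, function(t) mean(s[!pos] <= t), numeric(1)))
  structure(list(
    roc = roc,
    auc = auc, auc_ci = auc_ci,
    accuracy = mean(pred_pos == pos),
    sensitivity = if (any(pos)) mean(pred_pos[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(!pred_pos[!pos]) else NA_real_,
    threshold = model$threshold, degenerate = degenerate,
    n = length(y)),
    class = "classifier_report")
}

#' @export
plot.classifier_report <- function(x, ...) {
  graphics::plot(1 - x$roc$specificity, x$roc$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> AUC = %.3f (95%% CI %.3f-%.3f), accuracy %.2f, sensitivity %.2f, specificity %.2f%s\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$accuracy, x$sensitivity,
              x$specificity, if (x$degenerate) " [degenerate threshold]" else ""))
  invisible(x)
}
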