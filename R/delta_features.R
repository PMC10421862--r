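## Feature normalisation and post-minus-pre deltas.

feature_columns <- function(table) {
  setdiff(names(table), c("patient_id", "timepoint"))
}

#' Fit per-feature z-score normalization on a training feature table
#'
#' Means and SDs are estimated on the pooled pre+post training rows, so that
#' the two timepoints stay on one common scale. Features with zero variance
#' (or no finite values) are dropped with a warning.
#'
#' @param train_table feature table (`patient_id`, `timepoint`, features).
#' @return Object of class `normalization_stats` (`feature`, `mean`, `sd`,
#'   plus the dropped-feature names).
#' @export
fit_normalization <- function(train_table) {
  if (nrow(train_table) < 2L) stop("need at least 2 rows to fit normalization")
  cols <- feature_columns(train_table)
  mu <- vapply(cols, function(cl) mean(train_table[[cl]], na.rm = TRUE), numeric(1))
  sd_ <- vapply(cols, function(cl) stats::sd(train_table[[cl]], na.rm = TRUE), numeric(1))
  bad <- !is.finite(sd_) | sd_ == 0
  if (any(bad))
    warning(sum(bad), " zero-variance feature(s) dropped: ",
            paste(utils::head(cols[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
  structure(list(feature = cols[!bad], mean = mu[!bad], sd = sd_[!bad],
                 dropped = cols[bad]),
            class = "normalization_stats")
}

#' @rdname fit_normalization
#' @param table a feature table to transform with previously fitted stats
#'   (training stats are reused for validation cohorts; no leakage).
#' @param stats a `normalization_stats` object.
#' @export
apply_normalization <- function(table, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  miss <- setdiff(stats$feature, names(table))
  if (length(miss)) stop("table lacks normalized features: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  out <- table[, intersect(names(table), c("patient_id", "timepoint")), drop = FALSE]
  z <- sweep(sweep(as.matrix(table[, stats$feature, drop = FALSE]), 2,
                   stats$mean, "-"), 2, stats$sd, "/")
  cbind(out, as.data.frame(z))
}

#' Post-minus-pre feature deltas
#'
#' Aligns the two tables on `patient_id` and returns `post - pre` for every
#' shared feature column; an optional raw volume change (mL) is appended as
#' `volume_change_ml`.
#'
#' @param pre,post feature tables for the two timepoints (same patients, same
#'   feature columns).
#' @param volume_change optional numeric vector (one per patient, in `pre`
#'   patient order) appended as `volume_change_ml`.
#' @return data.frame: `patient_id` plus one delta column per feature.
#' @export
compute_delta <- function(pre, post, volume_change = NULL) {
  if (!setequal(pre$patient_id, post$patient_id) ||
      anyDuplicated(pre$patient_id) || anyDuplicated(post$patient_id))
    stop("patient mismatch between pre and post tables")
  cols <- setdiff(feature_columns(pre), "timepoint")
  if (!setequal(cols, setdiff(feature_columns(post), "timepoint")))
    stop("feature name mismatch between pre and post tables")
  post <- post[match(pre$patient_id, post$patient_id), , drop = FALSE]
  d <- as.matrix(post[, cols, drop = FALSE]) - as.matrix(pre[, cols, drop = FALSE])
  out <- data.frame(patient_id = pre$patient_id, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(d))
  if (!is.null(volume_change)) out$volume_change_ml <- volume_change
  out
}

#' Extract the full per-scan feature table of a cohort
#'
#' Runs region construction, the texture bank and the shape module on every
#' scan of a phantom cohort: one row per (patient, timepoint) with 1110
#' texture statistics and 24 shape features.
#'
#' @param cohort a [generate_cohort()] result with volumes.
#' @param rim_mm,fat_hu rim settings (see [extract_peritumoral_rim()]).
#' @param ... texture settings passed to [extract_texture_features()].
#' @return A feature table data.frame.
#' @export
extract_cohort_features <- function(cohort, rim_mm = 12, fat_hu = c(-100, -10),
                                    ...) {
  if (is.null(cohort$patients)) stop("cohort was generated without volumes")
  rows <- list()
  for (i in seq_along(cohort$patients)) {
    pid <- cohort$clinical$patient_id[i]
    for (tp in c("pre", "post")) {
      ph <- cohort$patients[[i]][[tp]]
      rp <- extract_peritumoral_rim(ph$volume, ph$mask, rim_mm = rim_mm,
                                    fat_hu = fat_hu)
      tex <- extract_texture_features(ph$volume, rp, ...)
      shp <- extract_shape_features(ph$mask)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, timepoint = tp,
        as.data.frame(t(c(tex, shp))), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build the delta feature table (normalize, then post-minus-pre)
#'
#' Fits (or reuses) z-score normalization, applies it to both timepoints and
#' differences them. By default features are normalized first and then
#' differenced; `order = "delta_first"` differences raw values and then
#' normalizes the deltas (sensitivity analysis).
#'
#' @param feature_table a per-scan feature table (both timepoints).
#' @param normalization training stats to reuse (validation cohorts); fitted
#'   on `feature_table` when `NULL`.
#' @param order `"normalize_first"` (default) or `"delta_first"`.
#' @return `list(delta = data.frame, normalization = normalization_stats)`;
#'   the delta table carries the raw `volume_change_ml` column.
#' @export
build_delta_table <- function(feature_table, normalization = NULL,
                              order = c("normalize_first", "delta_first")) {
  order <- match.arg(order)
  pre <- feature_table[feature_table$timepoint == "pre", , drop = FALSE]
  post <- feature_table[feature_table$timepoint == "post", , drop = FALSE]
  post <- post[match(pre$patient_id, post$patient_id), , drop = FALSE]
  vol_change <- if ("shape_volume_ml" %in% names(pre))
    post$shape_volume_ml - pre$shape_volume_ml else NULL
  if (order == "normalize_first") {
    if (is.null(normalization)) normalization <- fit_normalization(feature_table)
    delta <- compute_delta(apply_normalization(pre, normalization),
                           apply_normalization(post, normalization),
                           volume_change = vol_change)
  } else {
    raw_delta <- compute_delta(pre, post, volume_change = vol_change)
    dtab <- raw_delta[, setdiff(names(raw_delta), "volume_change_ml"), drop = FALSE]
    if (is.null(normalization)) normalization <- fit_normalization(dtab)
    delta <- apply_normalization(dtab, normalization)
    delta$volume_change_ml <- raw_delta$volume_change_ml
  }
  list(delta = delta, normalization = normalization)
}
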