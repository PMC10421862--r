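# Shared fixtures: all imaging fixtures are generated in code at test time.

# A compact phantom configuration that keeps per-test runtimes low while
# preserving all structural properties (lesion + rim fit with margin).
small_cohort_config <- function(n_patients = 4L, seed = 1L, ...) {
  cohort_config(n_patients = n_patients, dim = c(48L, 48L, 16L),
                lesion_radius_mm = c(5, 8), seed = seed, ...)
}

small_phantom <- function(seed = 1L, patient = 1L, timepoint = "pre", ...) {
  generate_phantom(small_cohort_config(seed = seed, ...), patient, timepoint)
}

# Brute-force GLCM oracle: enumerate every pixel pair at the offset by hand.
glcm_oracle <- function(slice, region, levels, offset, symmetric = TRUE) {
  q <- matrix(NA_integer_, nrow(slice), ncol(slice))
  q[region] <- quantize_levels(slice[region], levels)
  cnt <- matrix(0, levels, levels)
  for (r in seq_len(nrow(slice))) for (cc in seq_len(ncol(slice))) {
    r2 <- r + offset[1]; c2 <- cc + offset[2]
    if (r2 < 1 || r2 > nrow(slice) || c2 < 1 || c2 > ncol(slice)) next
    a <- q[r, cc]; b <- q[r2, c2]
    if (is.na(a) || is.na(b)) next
    cnt[a, b] <- cnt[a, b] + 1
    if (symmetric) cnt[b, a] <- cnt[b, a] + 1
  }
  if (sum(cnt) > 0) cnt / sum(cnt) else cnt
}

# Clinical table around a feature-matrix simulation.
sim_clinical <- function(sim) {
  n <- length(sim$time)
  data.frame(patient_id = rownames(sim$x) %||% as.character(seq_len(n)),
             os_months = sim$time, event = sim$event,
             response = "responder", age = 60, race = "White",
             baseline_tumor_volume_ml = 1, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
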