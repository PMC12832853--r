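#' Canonical feature names
#'
#' The 156-dimensional feature vector decomposes as 6 waveform features for
#' each of the 16 sensors (96), 4 whole-foot features per foot (8), a
#' bilateral symmetry index for each of the 6 waveform features at each of
#' the 8 sensor pairs (48), and a symmetry index for each whole-foot
#' feature (4). Order: sensor blocks L1..L8 then R1..R8, foot blocks L then
#' R, pair-SI blocks 1..8, foot-SI block.
#'
#' @return Character vector of 156 names, e.g. \code{"L1_FWHM"},
#'   \code{"R_TAP"}, \code{"3_FWHM_SI"}, \code{"COPX_SI"}.
#' @export
feature_names <- function() {
  sens <- c("PPP", "PTI", "maxPG", "minPG", "FWHM", "AP")
  foot <- c("TAP", "FR", "COPX", "COPY")
  c(
    as.vector(t(outer(channel_names(), sens, paste, sep = "_"))),
    as.vector(t(outer(c("L", "R"), foot, paste, sep = "_"))),
    as.vector(t(outer(1:8, paste0(sens, "_SI"), paste, sep = "_"))),
    paste0(foot, "_SI")
  )
}

#' Segment a series into whole gait cycles
#'
#' Consecutive non-overlapping windows of length \code{p} starting at the
#' first sample; the trailing partial window is discarded.
#'
#' @param x numeric vector.
#' @param p period in samples (>= 2).
#' @return A matrix with \code{p} rows, one column per cycle.
#' @export
segment_cycles <- function(x, p) {
  if (p < 2) stop_plantar("period must be at least 2 samples",
                          "segmentation_error")
  n_cyc <- length(x) %/% p
  if (n_cyc < 1)
    stop_plantar("series shorter than one gait cycle", "segmentation_error")
  matrix(x[seq_len(n_cyc * p)], nrow = p)
}

# FWHM of one cycle, in samples. Width of the contiguous region around the
# peak where x >= max(x)/2, with linearly interpolated crossings; where the
# region touches a cycle boundary without crossing, the boundary extends
# half a sample beyond the end sample (so a constant cycle spans p samples).
.fwhm_cycle <- function(x) {
  ppp <- max(x)
  if (ppp <= 0) return(0)
  half <- ppp / 2
  pk <- which.max(x)
  p <- length(x)
  # left boundary
  i <- pk
  while (i > 1 && x[i - 1] >= half) i <- i - 1
  left <- if (i == 1) 0.5 else i - (x[i] - half) / (x[i] - x[i - 1])
  # right boundary
  j <- pk
  while (j < p && x[j + 1] >= half) j <- j + 1
  right <- if (j == p) p + 0.5 else j + (x[j] - half) / (x[j] - x[j + 1])
  right - left
}

#' Per-sensor waveform features
#'
#' Six features per sensor, each computed per gait cycle and averaged over
#' complete cycles: peak pressure (PPP, N), pressure-time integral by the
#' trapezoidal rule (PTI, N s), maximum and minimum pressure gradients by
#' forward first difference (maxPG/minPG, N/s), full width at half maximum
#' of the pressure pulse (FWHM, s), and area-based average pressure (AP, N)
#' over samples above 5\% of the cycle peak. An all-zero cycle contributes
#' zero to every feature.
#'
#' @param x non-negative sensor series.
#' @param p unified gait period in samples.
#' @param fs sampling frequency in Hz.
#' @param ap_threshold activation threshold for AP as a fraction of the
#'   cycle peak.
#' @return Named numeric vector \code{c(PPP, PTI, maxPG, minPG, FWHM, AP)}.
#' @export
sensor_features <- function(x, p, fs, ap_threshold = 0.05) {
  cyc <- segment_cycles(x, p)
  per_cycle <- apply(cyc, 2, function(v) {
    ppp <- max(v)
    if (ppp <= 0)
      return(c(PPP = 0, PTI = 0, maxPG = 0, minPG = 0, FWHM = 0, AP = 0))
    d <- diff(v) * fs
    act <- v[v > ap_threshold * ppp]
    c(PPP = ppp,
      PTI = sum((v[-1] + v[-length(v)]) / 2) / fs,
      maxPG = if (length(d)) max(d) else 0,
      minPG = if (length(d)) min(d) else 0,
      FWHM = .fwhm_cycle(v) / fs,
      AP = if (length(act)) mean(act) else 0)
  })
  rowMeans(per_cycle)
}

#' Whole-foot features
#'
#' TAP: time mean of the foot's summed pressure over the recording's
#' complete gait cycles (N). F/R: cycle-mean ratio of the summed forefoot peak to the summed
#' rearfoot peak (0 when the rearfoot never loads). COPX/COPY: total
#' frame-to-frame displacement of the pressure-weighted centre of pressure
#' along each axis, counted over consecutive frames where the foot carries
#' load (> 1\% of the recording's maximum foot sum), normalised per
#' complete gait cycle.
#'
#' @param rec a \code{pressure_recording}.
#' @param foot \code{"L"} or \code{"R"}.
#' @param p unified gait period in samples.
#' @param layout a \code{sensor_layout}.
#' @param cop_threshold valid-frame threshold as a fraction of the maximum
#'   foot sum.
#' @details All four features operate on whole cycles phase-aligned to the
#'   quietest seam of the foot's folded pressure profile, so the stride
#'   phase of the recording does not leak into the features.
#' @return Named numeric vector \code{c(TAP, FR, COPX, COPY)}.
#' @export
foot_features <- function(rec, foot, p, layout = default_layout(),
                          cop_threshold = 0.01) {
  cols <- if (foot == "L") 1:8 else 9:16
  pm_full <- rec$pressure[, cols, drop = FALSE]

  # whole aligned cycles only, so both feet see the same stance geometry
  off <- .cycle_offset(rowSums(pm_full), p)
  n_cyc <- (nrow(pm_full) - off + 1) %/% p
  if (n_cyc < 1) {
    warning(sprintf("foot %s: recording shorter than one gait cycle", foot))
    return(c(TAP = mean(rowSums(pm_full)), FR = 0, COPX = 0, COPY = 0))
  }
  pm <- pm_full[off:(off + n_cyc * p - 1), , drop = FALSE]
  fsum <- rowSums(pm)
  tap <- mean(fsum)

  ff <- attr(layout, "forefoot_set")
  rf <- attr(layout, "rearfoot_set")
  fore <- rowSums(pm[, ff, drop = FALSE])
  rear <- rowSums(pm[, rf, drop = FALSE])
  fr_cyc <- vapply(seq_len(n_cyc), function(k) {
    idx <- ((k - 1) * p + 1):(k * p)
    rp <- max(rear[idx])
    if (rp <= 0) 0 else max(fore[idx]) / rp
  }, numeric(1))
  fr <- mean(fr_cyc)

  lay <- layout[layout$foot == foot, ]
  lay <- lay[order(lay$index), ]
  valid <- fsum > cop_threshold * max(fsum)
  copx <- copy <- 0
  if (any(valid)) {
    cx <- as.vector(pm %*% lay$x) / fsum
    cy <- as.vector(pm %*% lay$y) / fsum
    pair <- valid[-length(valid)] & valid[-1]
    if (any(pair)) {
      copx <- sum(abs(diff(cx))[pair]) / n_cyc
      copy <- sum(abs(diff(cy))[pair]) / n_cyc
    }
  } else {
    warning(sprintf("foot %s: no frames above COP threshold", foot))
  }
  c(TAP = tap, FR = fr, COPX = copx, COPY = copy)
}

#' Bilateral symmetry index
#'
#' \code{SI = |vL - vR| / ((|vL| + |vR|)/2) * 100}, in percent; defined 0
#' when both values are 0. Absolute values in the denominator make the
#' index well defined for signed features (minPG). For non-negative
#' features the index lies in [0, 200].
#'
#' @param v_left,v_right feature values (vectorised).
#' @return Symmetry index in percent.
#' @export
symmetry_index <- function(v_left, v_right) {
  denom <- (abs(v_left) + abs(v_right)) / 2
  ifelse(denom == 0, 0, abs(v_left - v_right) / denom * 100)
}

# Phase-align a foot's series to the quietest seam of its average cycle:
# fold the summed foot pressure over the period and start segmentation at
# the phase k minimising profile[k-1] + profile[k] (the mass of the
# boundary segment between consecutive windows). The cycle boundary is
# arbitrary for a cyclic waveform; cutting where the foot is unloaded
# keeps each stance pulse contiguous inside one window and puts the least
# possible signal on the seam the per-cycle integrals do not see, which
# makes the cycle-averaged features invariant to the stride phase of the
# recording (so the two feet, walking half a stride apart, are described
# identically when their waveforms match).
.cycle_offset <- function(fsum, p) {
  n_cyc <- length(fsum) %/% p
  if (n_cyc < 1) return(1L)
  profile <- rowMeans(matrix(fsum[seq_len(n_cyc * p)], nrow = p))
  seam <- profile[c(p, seq_len(p - 1))] + profile
  which.min(seam)
}

#' Extract the full 156-dimensional feature vector
#'
#' Runs period detection (foot sums, FFT + autocorrelation, unification),
#' then computes every feature family on the unified period. Each foot's
#' cycles are phase-aligned to the minimum of its folded pressure profile
#' before segmentation.
#'
#' @param rec a \code{pressure_recording}.
#' @param layout a \code{sensor_layout}.
#' @param period optional pre-computed unified period in samples (skips
#'   detection).
#' @param ... passed to \code{\link{detect_period_1d}}.
#' @return Named numeric vector of length 156 in \code{\link{feature_names}}
#'   order, with attribute \code{period} (the unified period used).
#' @export
extract_feature_vector <- function(rec, layout = default_layout(),
                                   period = NULL, ...) {
  if (is.null(period))
    period <- detect_gait_period(rec, ...)$period_unified
  fs <- rec$sample_rate

  s <- foot_sum(rec)
  off <- c(rep(.cycle_offset(s$left, period), 8),
           rep(.cycle_offset(s$right, period), 8))
  n <- nrow(rec$pressure)
  sens <- vapply(1:16, function(j)
    sensor_features(rec$pressure[off[j]:n, j], period, fs), numeric(6))
  # sens: 6 x 16 matrix, columns L1..L8,R1..R8

  foot_l <- foot_features(rec, "L", period, layout)
  foot_r <- foot_features(rec, "R", period, layout)

  si_pairs <- vapply(1:8, function(i)
    symmetry_index(sens[, i], sens[, i + 8]), numeric(6))
  si_foot <- symmetry_index(foot_l, foot_r)

  out <- c(as.vector(sens), foot_l, foot_r, as.vector(si_pairs), si_foot)
  names(out) <- feature_names()
  attr(out, "period") <- period
  out
}

#' Extract the feature matrix of a cohort
#'
#' @param cohort a \code{gait_cohort}.
#' @param layout a \code{sensor_layout}.
#' @param ... passed to \code{\link{extract_feature_vector}}.
#' @return Numeric matrix, one row per recording, 156 named columns, with
#'   attribute \code{periods} (unified period per recording).
#' @export
extract_features <- function(cohort, layout = default_layout(), ...) {
  fv <- lapply(cohort$recordings, extract_feature_vector, layout = layout, ...)
  x <- do.call(rbind, fv)
  rownames(x) <- cohort$subject_id
  attr(x, "periods") <- vapply(fv, function(v) as.numeric(attr(v, "period")),
                               numeric(1))
  x
}
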