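#' Synthetic gait cohort configuration
#'
#' The generator emulates quiet treadmill-style walking recorded by an
#' 8-sensor-per-foot insole at 20 Hz: each sensor emits one smooth
#' raised-cosine pulse per gait cycle at a region-specific stance phase
#' (heel early, midfoot mid-stance, metatarsal and hallux at push-off), the
#' two feet alternate by half a stride, and a latent balance score
#' \code{b in [0,1]} degrades the gait by adding cycle-time jitter, bilateral
#' amplitude asymmetry and sensor noise as \code{b} falls. BBS labels derive
#' from \code{b} through \code{\link{true_bbs}}, and a chosen fraction can be
#' corrupted with additive label noise to emulate unreliable clinical scoring.
#'
#' @param n_subjects number of subjects (one recording each by default).
#' @param duration recording length in seconds.
#' @param sample_rate sampling frequency in Hz.
#' @param stride_period_range range (s) from which each subject's stride
#'   period is drawn.
#' @param noise_sd additive sensor noise standard deviation (N) at b = 0;
#'   the effective sd scales with (1 - b).
#' @param asymmetry_gain bilateral amplitude asymmetry at b = 0
#'   (dimensionless fractional difference).
#' @param jitter_gain per-cycle period jitter (fraction of the stride
#'   period) at b = 0.
#' @param sensor_gain_sd log-normal sd of per-subject sensor gain
#'   multipliers (shared between feet, so asymmetry stays controlled by
#'   \code{asymmetry_gain} alone).
#' @param width_sd log-normal sd of per-subject pulse-width multipliers
#'   (shared between feet).
#' @param stance_broadening fractional pulse-width increase at b = 0:
#'   degraded balance prolongs stance contact.
#' @param load_shift fractional forefoot-to-rearfoot load redistribution
#'   at b = 0.
#' @param label_noise_frac fraction of labels to corrupt.
#' @param label_noise_range integer magnitude range (BBS points) of the
#'   corruption, sign uniform.
#' @param score_dependent if TRUE, low-BBS subjects are preferentially
#'   corrupted and the magnitude grows with (56 - BBS), emulating the larger
#'   scoring error observed at the low end of the scale.
#' @param body_weight nominal body weight (N) shared across regions.
#' @param k_repeats recordings per subject (repeated-measures mode).
#' @param seed integer seed; every stochastic choice flows from it.
#' @return A list of class \code{gen_config}.
#' @export
gen_config <- function(n_subjects = 131,
                       duration = 60,
                       sample_rate = 20,
                       stride_period_range = c(0.9, 1.4),
                       noise_sd = 1.0,
                       asymmetry_gain = 0.5,
                       jitter_gain = 0.04,
                       sensor_gain_sd = 0.15,
                       width_sd = 0.10,
                       stance_broadening = 0.25,
                       load_shift = 0.25,
                       label_noise_frac = 0,
                       label_noise_range = c(5L, 15L),
                       score_dependent = FALSE,
                       body_weight = 600,
                       k_repeats = 1,
                       seed = 1) {
  stopifnot(label_noise_frac >= 0, label_noise_frac <= 1,
            all(stride_period_range > 0), duration > 0, sample_rate > 0)
  structure(list(n_subjects = n_subjects, duration = duration,
                 sample_rate = sample_rate,
                 stride_period_range = stride_period_range,
                 noise_sd = noise_sd, asymmetry_gain = asymmetry_gain,
                 jitter_gain = jitter_gain,
                 sensor_gain_sd = sensor_gain_sd, width_sd = width_sd,
                 stance_broadening = stance_broadening,
                 load_shift = load_shift,
                 label_noise_frac = label_noise_frac,
                 label_noise_range = as.integer(label_noise_range),
                 score_dependent = score_dependent,
                 body_weight = body_weight, k_repeats = k_repeats,
                 seed = as.integer(seed)),
            class = "gen_config")
}

# Stance-phase windows (fraction of the gait cycle) and load shares per
# sensor, in layout index order. The windows encode the heel-to-toe loading
# progression; the shares are plausible static proportions, not claims about
# any particular cohort.
.pulse_phase <- matrix(c(
  0.60, 0.90,   # 1 hallux
  0.45, 0.80,   # 2 1st metatarsal
  0.45, 0.80,   # 3 3rd metatarsal
  0.48, 0.82,   # 4 5th metatarsal
  0.25, 0.55,   # 5 medial midfoot
  0.25, 0.55,   # 6 lateral midfoot
  0.05, 0.35,   # 7 medial heel
  0.05, 0.35    # 8 lateral heel
), ncol = 2, byrow = TRUE)

.load_share <- c(0.10, 0.12, 0.10, 0.08, 0.05, 0.05, 0.26, 0.24)

#' Generate one synthetic recording
#'
#' @param b latent balance in [0, 1] (1 = perfect balance).
#' @param cfg a \code{\link{gen_config}}.
#' @param stride_period stride period in seconds; drawn from
#'   \code{cfg$stride_period_range} when NULL.
#' @param subject_id identifier for the recording.
#' @return A list with \code{recording} (a \code{pressure_recording}) and
#'   \code{truth} (one-row data frame: true stride period in samples,
#'   asymmetry level, b).
#' @export
generate_recording <- function(b, cfg = gen_config(), stride_period = NULL,
                               subject_id = "synth") {
  stopifnot(b >= 0, b <= 1)
  fs <- cfg$sample_rate
  n  <- round(cfg$duration * fs)
  if (is.null(stride_period))
    stride_period <- stats::runif(1, cfg$stride_period_range[1],
                                  cfg$stride_period_range[2])
  p_samp <- round_half_up(stride_period * fs)
  period <- p_samp / fs  # snap to whole samples so the cycle is resolvable

  deg <- 1 - b
  jitter_sd <- cfg$jitter_gain * deg * period
  asym <- cfg$asymmetry_gain * deg          # fractional L/R amplitude gap
  amp_l <- 1 + asym / 2
  amp_r <- 1 - asym / 2

  # per-subject biomechanical individuality, shared between feet so that
  # bilateral differences remain governed by asymmetry_gain alone
  gains <- exp(stats::rnorm(8, 0, cfg$sensor_gain_sd))
  widths <- exp(stats::rnorm(8, 0, cfg$width_sd)) *
    (1 + cfg$stance_broadening * deg)       # low balance prolongs contact
  # low balance shifts load from forefoot onto the heel
  share <- .load_share
  share[1:4] <- share[1:4] * (1 - cfg$load_shift * deg)
  share[7:8] <- share[7:8] * (1 + cfg$load_shift * deg)

  # cycle onset times with zero-mean per-cycle jitter; phase is piecewise
  # linear between onsets so the average rate stays 1/period
  n_cyc <- ceiling(cfg$duration / period) + 2
  onsets <- (seq_len(n_cyc + 1) - 1) * period
  if (jitter_sd > 0)
    onsets[-1] <- onsets[-1] + stats::rnorm(n_cyc, 0, jitter_sd)
  onsets <- sort(onsets)

  t <- (seq_len(n) - 1) / fs
  cyc <- findInterval(t, onsets, rightmost.closed = FALSE)
  cyc[cyc < 1] <- 1
  phase <- (t - onsets[cyc]) / pmax(onsets[cyc + 1] - onsets[cyc], 1e-9)
  phase <- pmin(pmax(phase, 0), 1)

  pulse <- function(ph, win) {
    u <- (ph - win[1]) / (win[2] - win[1])
    ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
  }

  press <- matrix(0, n, 16)
  phase_r <- (phase + 0.5) %% 1  # right foot leads by half a stride
  for (s in 1:8) {
    ctr <- mean(.pulse_phase[s, ])
    hw <- diff(.pulse_phase[s, ]) / 2 * widths[s]
    win <- pmin(pmax(c(ctr - hw, ctr + hw), 0), 1)
    a <- cfg$body_weight * share[s] * gains[s]
    press[, s]     <- a * amp_l * pulse(phase,   win)
    press[, s + 8] <- a * amp_r * pulse(phase_r, win)
  }
  if (cfg$noise_sd > 0) {
    sd_eff <- cfg$noise_sd * (0.3 + 0.7 * deg)
    press <- press + matrix(stats::rnorm(n * 16, 0, sd_eff), n, 16)
  }
  press[press < 0] <- 0

  rec <- suppressWarnings(
    pressure_recording(press, sample_rate = fs, subject_id = subject_id))
  list(recording = rec,
       truth = data.frame(subject_id = subject_id, b = b,
                          stride_period_samples = p_samp,
                          asymmetry = asym))
}

#' Map a latent balance score to a true BBS score
#'
#' Monotone non-decreasing map \code{round(56 * b^gamma)} clamped to the
#' 0--56 BBS range.
#'
#' @param b latent balance in [0, 1] (vectorised).
#' @param gamma shape exponent (1 = linear).
#' @return Integer BBS scores in [0, 56].
#' @export
true_bbs <- function(b, gamma = 1) {
  stopifnot(all(b >= 0 & b <= 1))
  pmin(56L, pmax(0L, as.integer(round_half_up(56 * b^gamma))))
}

#' Inject additive label noise
#'
#' Exactly \code{round(rho * n)} labels (half-up) are perturbed by a random
#' magnitude with uniform sign and clamped to [0, 56]. In score-dependent
#' mode the corrupted subjects are drawn with probability proportional to
#' \code{56 - y + 1} and the magnitude is scaled by \code{(56 - y)/56},
#' so low scores carry more noise.
#'
#' @param labels integer BBS labels in [0, 56].
#' @param rho fraction of labels to corrupt.
#' @param magnitude_range integer range of perturbation magnitudes.
#' @param score_dependent logical; see Description.
#' @return A list: \code{noisy} (perturbed labels), \code{is_noisy}
#'   (logical indicator).
#' @export
inject_label_noise <- function(labels, rho, magnitude_range = c(5L, 15L),
                               score_dependent = FALSE) {
  stopifnot(rho >= 0, rho <= 1)
  n <- length(labels)
  k <- as.integer(round_half_up(rho * n))
  noisy <- as.integer(labels)
  ind <- rep(FALSE, n)
  if (k > 0) {
    w <- if (score_dependent) (56 - labels + 1) else rep(1, n)
    idx <- sample.int(n, k, prob = w)
    mags <- seq(magnitude_range[1], magnitude_range[2])
    mag <- mags[sample.int(length(mags), k, replace = TRUE)]
    if (score_dependent)
      mag <- pmax(1L, as.integer(round_half_up(mag * (56 - labels[idx]) / 56)))
    sgn <- sample(c(-1L, 1L), k, replace = TRUE)
    noisy[idx] <- pmin(56L, pmax(0L, labels[idx] + sgn * mag))
    ind[idx] <- TRUE
  }
  list(noisy = noisy, is_noisy = ind)
}

#' Generate a full synthetic cohort
#'
#' Draws a latent balance per subject, synthesises recordings, assigns BBS
#' labels via \code{\link{true_bbs}}, splits into train/test, and injects
#' label noise into the training labels only.
#'
#' @param cfg a \code{\link{gen_config}}.
#' @param n_test number of test subjects (generated in addition to
#'   \code{cfg$n_subjects} training subjects; test labels are never
#'   corrupted).
#' @return A \code{gait_cohort} with an extra \code{truth} data frame
#'   (per-recording: b, true BBS, noisy BBS, noisy indicator, stride period,
#'   asymmetry).
#' @export
generate_cohort <- function(cfg = gen_config(), n_test = 29) {
  set.seed(cfg$seed)
  n_subj <- cfg$n_subjects + n_test
  b <- stats::runif(n_subj, 0.15, 1)
  # repeated-measures mode reuses a subject's latent for its k recordings
  reps <- rep(seq_len(n_subj), each = cfg$k_repeats)
  n_rec <- length(reps)
  split <- rep(c("train", "test"),
               c(cfg$n_subjects * cfg$k_repeats, n_test * cfg$k_repeats))
  ids <- sprintf("S%03d%s", reps,
                 if (cfg$k_repeats > 1)
                   paste0("r", sequence(rep(cfg$k_repeats, n_subj))) else "")
  recs <- vector("list", n_rec)
  truth <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    g <- generate_recording(b[reps[i]], cfg, subject_id = ids[i])
    recs[[i]] <- g$recording
    truth[[i]] <- g$truth
  }
  truth <- do.call(rbind, truth)
  truth$true_bbs <- true_bbs(truth$b)
  is_tr <- split == "train"
  noise <- inject_label_noise(truth$true_bbs[is_tr], cfg$label_noise_frac,
                              cfg$label_noise_range, cfg$score_dependent)
  truth$noisy_bbs <- truth$true_bbs
  truth$noisy_bbs[is_tr] <- noise$noisy
  truth$is_noisy <- FALSE
  truth$is_noisy[is_tr] <- noise$is_noisy
  structure(list(recordings = recs,
                 bbs        = as.integer(truth$noisy_bbs),
                 labeled    = rep(TRUE, n_rec),
                 split      = factor(split, levels = c("train", "test")),
                 subject_id = ids,
                 truth      = truth),
            class = "gait_cohort")
}

#' Write a cohort (recordings + manifest + truth) to a directory
#'
#' @param cohort a \code{gait_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("%s.csv", cohort$subject_id)
  for (i in seq_along(cohort$recordings))
    write_recording(cohort$recordings[[i]], file.path(dir, paths[i]))
  manifest <- data.frame(subject_id = cohort$subject_id,
                         recording_path = paths,
                         bbs_score = cohort$bbs,
                         split = as.character(cohort$split))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", digits = NA)
  invisible(dir)
}
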