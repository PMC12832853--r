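#' Construct a plantar-pressure recording
#'
#' A recording is the raw unit of data: a T x 16 matrix of pressures in
#' Newtons sampled at \code{sample_rate} Hz, columns \code{L1..L8, R1..R8}
#' following the sensor layout index order.
#'
#' @param pressure numeric T x 16 matrix, non-negative, columns L1..L8,R1..R8.
#' @param sample_rate sampling frequency in Hz (default 20).
#' @param subject_id subject identifier string.
#' @return An object of class \code{pressure_recording} with elements
#'   \code{subject_id}, \code{sample_rate}, \code{pressure}, \code{duration}.
#' @export
pressure_recording <- function(pressure, sample_rate = 20,
                               subject_id = "anon") {
  pressure <- as.matrix(pressure)
  if (ncol(pressure) != 16)
    stop_plantar("recording must have exactly 16 channels", "format_error")
  if (any(!is.finite(pressure)))
    stop_plantar("pressure matrix contains non-finite values",
                 "validation_error")
  if (any(pressure < 0)) {
    warning("negative pressure readings clipped to 0")
    pressure[pressure < 0] <- 0
  }
  colnames(pressure) <- channel_names()
  structure(list(subject_id  = subject_id,
                 sample_rate = sample_rate,
                 pressure    = pressure,
                 duration    = nrow(pressure) / sample_rate),
            class = "pressure_recording")
}

channel_names <- function() {
  c(paste0("L", 1:8), paste0("R", 1:8))
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf("<pressure_recording> subject %s: %d samples x 16 channels, %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$pressure), x$sample_rate, x$duration))
  invisible(x)
}

#' Read a recording from CSV
#'
#' Expects a header \code{time,L1,...,L8,R1,...,R8} with time in seconds.
#' Sampling must be uniform to within 1\% jitter of the median interval;
#' negative readings are clipped to zero with a warning.
#'
#' @param path CSV file path.
#' @param subject_id identifier to attach (default: file stem).
#' @return A \code{pressure_recording}.
#' @export
read_recording <- function(path, subject_id = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("time", channel_names())
  if (!all(need %in% names(d)))
    stop_plantar(sprintf("recording CSV must have columns %s",
                         paste(need, collapse = ",")), "format_error")
  tm <- d$time
  if (length(tm) >= 2) {
    dt <- diff(tm)
    if (any(dt <= 0))
      stop_plantar("timestamps must be strictly increasing", "sampling_error")
    med <- stats::median(dt)
    if (any(abs(dt - med) > 0.01 * med))
      stop_plantar("non-uniform sampling beyond 1% jitter", "sampling_error")
    fs <- 1 / med
  } else {
    fs <- 20
  }
  pressure_recording(as.matrix(d[, channel_names(), drop = FALSE]),
                     sample_rate = fs,
                     subject_id = subject_id %||%
                       sub("\\.csv$", "", basename(path)))
}

#' Write a recording to CSV
#'
#' Inverse of \code{\link{read_recording}}; the round trip is lossless
#' (values are written with full precision).
#'
#' @param rec a \code{pressure_recording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pressure_recording"))
  if (any(!is.finite(rec$pressure)))
    stop_plantar("recording contains non-finite values", "validation_error")
  n <- nrow(rec$pressure)
  tm <- if (n > 0) (seq_len(n) - 1) / rec$sample_rate else numeric(0)
  d <- data.frame(time = tm)
  d[channel_names()] <- as.data.frame(rec$pressure)[channel_names()]
  # format with full precision so read -> write -> read is bit-exact
  utils::write.csv(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a cohort from a manifest CSV
#'
#' The manifest has columns \code{subject_id,recording_path,bbs_score,split}.
#' Recording paths are resolved relative to the manifest's directory. Rows
#' with a missing BBS score are loaded with an unlabeled mask; scores outside
#' 0--56 are rejected.
#'
#' @param manifest path to the manifest CSV.
#' @return A list of class \code{gait_cohort}: \code{recordings} (list of
#'   \code{pressure_recording}), \code{bbs} (integer, NA = unlabeled),
#'   \code{labeled} (logical mask), \code{split} (factor train/test),
#'   \code{subject_id}.
#' @export
load_cohort <- function(manifest) {
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "recording_path", "bbs_score", "split")
  if (!all(need %in% names(m)))
    stop_plantar("manifest must have columns subject_id,recording_path,bbs_score,split",
                 "format_error")
  bbs <- suppressWarnings(as.numeric(m$bbs_score))
  bad <- !is.na(bbs) & (bbs < 0 | bbs > 56 | bbs != round(bbs))
  if (any(bad))
    stop_plantar(sprintf("BBS score out of [0,56] for subject %s",
                         m$subject_id[which(bad)[1]]), "label_error")
  base <- dirname(manifest)
  recs <- lapply(seq_len(nrow(m)), function(i) {
    p <- m$recording_path[i]
    if (!file.exists(p)) p <- file.path(base, m$recording_path[i])
    read_recording(p, subject_id = m$subject_id[i])
  })
  out <- structure(list(recordings = recs,
                        bbs        = as.integer(bbs),
                        labeled    = !is.na(bbs),
                        split      = factor(m$split, levels = c("train", "test")),
                        subject_id = m$subject_id),
                   class = "gait_cohort")
  message(sprintf("loaded cohort: %d train, %d test",
                  sum(out$split == "train"), sum(out$split == "test")))
  out
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d recordings (%d train / %d test), %d labeled\n",
              length(x$recordings), sum(x$split == "train"),
              sum(x$split == "test"), sum(x$labeled)))
  invisible(x)
}
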