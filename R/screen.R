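#' Label-screening configuration
#'
#' Settings for the multi-model label-noise screen: three probe regressors
#' (ordinary least squares, linear-kernel SVR, RBF-kernel SVR) are each run
#' in several randomised replicates; within a replicate the model is
#' refitted a few times on random subsamples and every sample's absolute
#' prediction error is averaged. Samples whose error exceeds the 50th
#' percentile form one candidate set per model-replicate; a sample flagged
#' in at least \code{consensus_min_count} of the 3 x 4 = 12 sets is
#' declared anomalous.
#'
#' @param probe_models probe regressor kinds.
#' @param n_replicates_per_model randomised replicates per model.
#' @param n_repeats_per_replicate subsampled refits averaged within a
#'   replicate.
#' @param error_percentile candidate threshold percentile of the error
#'   distribution.
#' @param consensus_min_count flag-count threshold in frequency mode.
#' @param consensus_mode \code{"frequency"} (count over all model-replicate
#'   sets) or \code{"strict_all_models"} (intersection of the three
#'   models' replicate-averaged candidate sets).
#' @param subsample_frac training-subsample fraction per refit.
#' @param svr_cost,svr_epsilon SVR hyperparameters.
#' @param seed integer seed.
#' @return A list of class \code{screen_config}.
#' @export
screen_config <- function(probe_models = c("ols", "svr_linear", "svr_rbf"),
                          n_replicates_per_model = 4,
                          n_repeats_per_replicate = 3,
                          error_percentile = 50,
                          consensus_min_count = 8,
                          consensus_mode = c("frequency", "strict_all_models"),
                          subsample_frac = 0.8,
                          svr_cost = 1.0,
                          svr_epsilon = 0.1,
                          seed = 1) {
  consensus_mode <- match.arg(consensus_mode)
  stopifnot(error_percentile > 0, error_percentile < 100,
            consensus_min_count <=
              length(probe_models) * n_replicates_per_model,
            subsample_frac > 0, subsample_frac <= 1)
  structure(list(probe_models = probe_models,
                 n_replicates_per_model = n_replicates_per_model,
                 n_repeats_per_replicate = n_repeats_per_replicate,
                 error_percentile = error_percentile,
                 consensus_min_count = consensus_min_count,
                 consensus_mode = consensus_mode,
                 subsample_frac = subsample_frac,
                 svr_cost = svr_cost, svr_epsilon = svr_epsilon,
                 seed = as.integer(seed)),
            class = "screen_config")
}

.fit_probe <- function(x, y, kind, cfg) {
  if (kind == "ols") {
    fit <- tryCatch(stats::lm.fit(cbind(1, x), y), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      # rank-deficient design: tiny ridge keeps the probe defined
      warning("singular OLS probe fit; falling back to ridge (eps = 1e-8)")
      xa <- cbind(1, x)
      co <- solve(crossprod(xa) + diag(1e-8, ncol(xa)), crossprod(xa, y))
    } else {
      co <- fit$coefficients
    }
    function(newx) as.vector(cbind(1, newx) %*% co)
  } else {
    kern <- if (kind == "svr_linear") "linear" else "radial"
    gamma <- 1 / (ncol(x) * max(stats::var(as.vector(x)), 1e-12))
    fit <- e1071::svm(x, y, type = "eps-regression", kernel = kern,
                      cost = cfg$svr_cost, epsilon = cfg$svr_epsilon,
                      gamma = gamma, scale = FALSE)
    function(newx) as.vector(stats::predict(fit, newx))
  }
}

#' Per-sample probe errors for one model replicate
#'
#' Within a replicate, \code{cfg$n_repeats_per_replicate} random
#' fold partitions are drawn; for each, the probe is refitted on every
#' \code{subsample_frac} training complement and each sample's absolute
#' error is taken from the refit that held it out. Scoring samples
#' out-of-fold keeps the error informative even for probes flexible
#' enough to interpolate their training rows (with more features than
#' samples, least squares fits the subsample exactly, so an in-sample
#' error would say nothing about label quality). The per-sample errors
#' are averaged over the repeats.
#'
#' @param x standardized feature matrix (N x d).
#' @param y BBS labels.
#' @param kind one of \code{"ols"}, \code{"svr_linear"}, \code{"svr_rbf"}.
#' @param cfg a \code{\link{screen_config}}.
#' @return Numeric vector of N mean absolute errors.
#' @export
probe_errors <- function(x, y, kind, cfg = screen_config()) {
  n <- nrow(x)
  n_folds <- max(2, round(1 / (1 - cfg$subsample_frac)))
  err <- matrix(0, n, cfg$n_repeats_per_replicate)
  for (r in seq_len(cfg$n_repeats_per_replicate)) {
    fold <- sample(rep_len(seq_len(n_folds), n))
    for (f in seq_len(n_folds)) {
      idx <- which(fold != f)
      pred <- .fit_probe(x[idx, , drop = FALSE], y[idx], kind, cfg)
      out <- which(fold == f)
      err[out, r] <- abs(pred(x[out, , drop = FALSE]) - y[out])
    }
  }
  rowMeans(err)
}

#' Candidate anomaly set from an error vector
#'
#' Threshold is the requested percentile of the errors (linear
#' interpolation between order statistics); candidates are the samples with
#' error strictly greater than the threshold. With N distinct errors and
#' the 50th percentile this yields exactly floor(N/2) candidates.
#'
#' @param errors per-sample errors.
#' @param percentile threshold percentile (0-100).
#' @return Integer vector of candidate indices.
#' @export
candidate_set <- function(errors, percentile = 50) {
  stopifnot(length(errors) >= 2)
  thr <- stats::quantile(errors, percentile / 100, names = FALSE, type = 7)
  which(errors > thr)
}

#' Consensus over candidate sets
#'
#' Frequency mode counts, for each sample, the number of model-replicate
#' candidate sets containing it and flags counts at or above
#' \code{cfg$consensus_min_count}. Strict mode intersects one aggregate set
#' per model.
#'
#' @param candidate_sets list of integer index vectors.
#' @param cfg a \code{\link{screen_config}}.
#' @param n total number of samples (for the frequency table).
#' @return A list: \code{anomaly} (flagged indices), \code{frequency}
#'   (per-sample flag count, frequency mode only).
#' @export
consensus <- function(candidate_sets, cfg = screen_config(), n = NULL) {
  if (cfg$consensus_mode == "strict_all_models") {
    anomaly <- Reduce(intersect, candidate_sets)
    return(list(anomaly = sort(as.integer(anomaly)), frequency = NULL))
  }
  if (is.null(n)) n <- max(0, unlist(candidate_sets))
  freq <- tabulate(unlist(candidate_sets), nbins = n)
  list(anomaly = which(freq >= cfg$consensus_min_count), frequency = freq)
}

#' Screen a labeled training set for anomalous labels
#'
#' Full orchestration: for each probe model, \code{n_replicates_per_model}
#' replicates of subsampled refitting produce error vectors; each error
#' vector yields one candidate set at the percentile threshold; the
#' consensus rule produces the final anomaly set. Anomalous samples keep
#' their feature rows but have their labels masked (moved to the unlabeled
#' set); their original scores are discarded.
#'
#' @param x standardized feature matrix (training rows).
#' @param y BBS labels.
#' @param cfg a \code{\link{screen_config}}.
#' @return An object of class \code{screen_result}: \code{anomaly}
#'   (indices), \code{labeled_mask}, \code{unlabeled_mask} (logical,
#'   partitioning the training rows), \code{frequency}, \code{errors}
#'   (per-model mean error matrix), \code{candidate_sets}, \code{config}.
#' @export
screen_labels <- function(x, y, cfg = screen_config()) {
  stopifnot(nrow(x) == length(y))
  set.seed(cfg$seed)
  n <- nrow(x)
  sets <- list()
  err_by_model <- list()
  for (kind in cfg$probe_models) {
    errs <- matrix(0, n, cfg$n_replicates_per_model)
    for (rep_i in seq_len(cfg$n_replicates_per_model)) {
      e <- probe_errors(x, y, kind, cfg)
      errs[, rep_i] <- e
      sets[[length(sets) + 1]] <- candidate_set(e, cfg$error_percentile)
    }
    err_by_model[[kind]] <- rowMeans(errs)
  }
  if (cfg$consensus_mode == "strict_all_models") {
    model_sets <- lapply(err_by_model, candidate_set,
                         percentile = cfg$error_percentile)
    cons <- consensus(model_sets, cfg, n = n)
  } else {
    cons <- consensus(sets, cfg, n = n)
  }
  anomaly <- cons$anomaly
  labeled <- rep(TRUE, n)
  labeled[anomaly] <- FALSE
  structure(list(anomaly = anomaly,
                 labeled_mask = labeled,
                 unlabeled_mask = !labeled,
                 frequency = cons$frequency,
                 errors = do.call(cbind, err_by_model),
                 candidate_sets = sets,
                 config = cfg),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d of %d samples flagged as anomalously labeled (%s consensus)\n",
              length(x$anomaly), length(x$labeled_mask),
              x$config$consensus_mode))
  invisible(x)
}
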