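#' Pipeline configuration
#'
#' Bundles the per-stage configurations for an end-to-end run: synthetic
#' cohort generation (or an externally loaded cohort), feature extraction,
#' normalization, label screening, two-step feature selection, and
#' semi-supervised training with a fully supervised baseline for
#' comparison.
#'
#' @param gen a \code{\link{gen_config}} (used when no cohort is supplied).
#' @param n_test test-split size for generated cohorts.
#' @param screen a \code{\link{screen_config}}.
#' @param k_features final subset size.
#' @param r_max correlation-pruning threshold.
#' @param exclude_patterns rule-exclusion glob patterns.
#' @param lambda_u,sigma_delta,learning_rate,max_iter SSL training settings.
#' @param clamp clamp predictions to [0, 56] in evaluation.
#' @param seed run seed, propagated to every stage.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(gen = gen_config(label_noise_frac = 42 / 131),
                            n_test = 29,
                            screen = screen_config(),
                            k_features = 10,
                            r_max = 0.8,
                            exclude_patterns = c("*_minPG", "*_minPG_SI"),
                            lambda_u = 1.0, sigma_delta = 0.1,
                            learning_rate = 1e-2, max_iter = 5000,
                            clamp = FALSE,
                            seed = 1) {
  gen$seed <- as.integer(seed)
  screen$seed <- as.integer(seed)
  structure(list(gen = gen, n_test = n_test, screen = screen,
                 k_features = k_features, r_max = r_max,
                 exclude_patterns = exclude_patterns,
                 lambda_u = lambda_u, sigma_delta = sigma_delta,
                 learning_rate = learning_rate, max_iter = max_iter,
                 clamp = clamp, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full balance-assessment pipeline
#'
#' Stage order: cohort (generate or use the one supplied) -> gait-period
#' detection + 156-feature extraction -> Z-score normalization (fit on the
#' training group) -> multi-model label screening (flagged labels masked)
#' -> rule exclusion + correlation pruning + LASSO selection on the
#' surviving labeled samples -> consistency-regularized SSL training on the
#' selected features -> evaluation on the test split, alongside a fully
#' supervised least-squares baseline trained on all original training
#' labels.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @param cohort optional \code{gait_cohort}; generated synthetically when
#'   NULL.
#' @param layout a \code{sensor_layout}.
#' @param verbose print one line per stage.
#' @return An object of class \code{run_report}; see Details. Contains the
#'   stage artifacts (features, screen result, selection, the fitted
#'   \code{cssl} model, the baseline) and train/test \code{eval_report}s
#'   for both models.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL,
                         layout = default_layout(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(cohort)) {
    cohort <- generate_cohort(cfg$gen, n_test = cfg$n_test)
    say("stage cohort: generated %d recordings (seed %d)",
        length(cohort$recordings), cfg$seed)
  }
  is_tr <- cohort$split == "train"
  has_test <- any(!is_tr)
  if (!has_test) warning("cohort has no test split; evaluation skipped")

  x <- extract_features(cohort, layout)
  say("stage features: %d x %d matrix", nrow(x), ncol(x))

  x_tr <- x[is_tr, , drop = FALSE]
  y_tr <- cohort$bbs[is_tr]
  norm <- fit_normalizer(x_tr)
  z_tr <- predict(norm, x_tr)

  scr <- screen_labels(z_tr, y_tr, cfg$screen)
  say("stage screen: %d anomalies -> %d labeled + %d unlabeled",
      length(scr$anomaly), sum(scr$labeled_mask), sum(scr$unlabeled_mask))

  sel <- select_features(z_tr[scr$labeled_mask, , drop = FALSE],
                         y_tr[scr$labeled_mask],
                         k = cfg$k_features, r_max = cfg$r_max,
                         exclude_patterns = cfg$exclude_patterns,
                         seed = cfg$seed)
  say("stage select: %s", paste(sel$selected, collapse = ", "))

  zs_l <- z_tr[scr$labeled_mask, sel$selected, drop = FALSE]
  zs_u <- z_tr[scr$unlabeled_mask, sel$selected, drop = FALSE]
  model <- cssl(zs_l, y_tr[scr$labeled_mask], zs_u,
                lambda_u = cfg$lambda_u, sigma_delta = cfg$sigma_delta,
                learning_rate = cfg$learning_rate, max_iter = cfg$max_iter,
                seed = cfg$seed, clamp = cfg$clamp)

  # fully supervised baseline: least squares on all original training
  # labels over the same selected features
  bl <- stats::lm.fit(cbind(1, z_tr[, sel$selected, drop = FALSE]), y_tr)
  baseline <- list(w = bl$coefficients[-1], b = bl$coefficients[1])

  pred_with <- function(w, b, z) as.vector(z %*% w) + b
  ev <- list(
    ssl_train = evaluate(y_tr, predict(model, z_tr[, sel$selected,
                                                   drop = FALSE])),
    sup_train = evaluate(y_tr, pred_with(baseline$w, baseline$b,
                                         z_tr[, sel$selected, drop = FALSE]))
  )
  if (has_test) {
    z_te <- predict(norm, x[!is_tr, , drop = FALSE])[, sel$selected,
                                                     drop = FALSE]
    y_te <- cohort$bbs[!is_tr]
    ev$ssl_test <- evaluate(y_te, predict(model, z_te))
    ev$sup_test <- evaluate(y_te, pred_with(baseline$w, baseline$b, z_te))
  }
  say("stage eval: SSL test RMSE %s vs supervised %s",
      if (has_test) sprintf("%.3f", ev$ssl_test$rmse) else "-",
      if (has_test) sprintf("%.3f", ev$sup_test$rmse) else "-")

  structure(list(config = cfg,
                 n_train = sum(is_tr), n_test = sum(!is_tr),
                 periods = attr(x, "periods"),
                 features = x,
                 normalizer = norm,
                 screen = scr,
                 n_labeled = sum(scr$labeled_mask),
                 n_unlabeled = sum(scr$unlabeled_mask),
                 selection = sel,
                 model = model,
                 baseline = baseline,
                 evaluation = ev,
                 truth = cohort$truth),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> plantar-pressure balance-assessment pipeline\n")
  cat(sprintf("  cohort: %d train (%d labeled / %d masked) + %d test\n",
              x$n_train, x$n_labeled, x$n_unlabeled, x$n_test))
  cat(sprintf("  selected features: %s\n",
              paste(x$selection$selected, collapse = ", ")))
  cat(sprintf("  SSL        train %s",
              format_eval(x$evaluation$ssl_train)))
  if (!is.null(x$evaluation$ssl_test))
    cat(sprintf("  test %s", format_eval(x$evaluation$ssl_test)))
  cat("\n")
  cat(sprintf("  supervised train %s",
              format_eval(x$evaluation$sup_train)))
  if (!is.null(x$evaluation$sup_test))
    cat(sprintf("  test %s", format_eval(x$evaluation$sup_test)))
  cat("\n")
  invisible(x)
}

format_eval <- function(ev) {
  sprintf("RMSE %.2f MAE %.2f R2 %s", ev$rmse, ev$mae,
          if (is.na(ev$r2)) "NA" else sprintf("%.3f", ev$r2))
}

#' Replicated SSL-vs-supervised comparison
#'
#' Runs the full pipeline and the supervised baseline on freshly generated
#' noisy synthetic cohorts, one per seed, and tabulates test RMSEs. The
#' interesting quantity is the qualitative relation — how often masking
#' suspect labels and exploiting them through the consistency loss beats
#' training on all labels as-is.
#'
#' @param seeds integer vector of run seeds (>= 5).
#' @param cfg a \code{\link{pipeline_config}} template; its seed is
#'   overridden per run.
#' @return A data frame of class \code{replicate_summary} with one row per
#'   seed: test RMSE of the SSL pipeline and of the supervised baseline,
#'   their difference, and the anomaly count.
#' @export
replicate_experiment <- function(seeds, cfg = pipeline_config()) {
  stopifnot(length(seeds) >= 5)
  rows <- lapply(seeds, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(s)
    cfg_s$gen$seed <- as.integer(s)
    cfg_s$screen$seed <- as.integer(s)
    rep <- run_pipeline(cfg_s)
    data.frame(seed = s,
               rmse_ssl = rep$evaluation$ssl_test$rmse,
               rmse_supervised = rep$evaluation$sup_test$rmse,
               delta = rep$evaluation$ssl_test$rmse -
                 rep$evaluation$sup_test$rmse,
               n_anomalies = rep$n_unlabeled)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("replicate_summary", "data.frame")
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  wins <- mean(x$rmse_ssl <= x$rmse_supervised)
  cat(sprintf("SSL <= supervised in %.0f%% of %d runs (mean delta %+.3f)\n",
              100 * wins, nrow(x), mean(x$delta)))
  invisible(x)
}
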