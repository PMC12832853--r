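#' Fit a Z-score normalizer on training data
#'
#' Per-feature standardization z = (x - mu) / sigma with mean and sample
#' standard deviation estimated on the training group only; test data must
#' be transformed with the training parameters. A constant column gets
#' sigma := 1 (its standardized values are all zero) with a warning.
#'
#' @param x_train numeric training feature matrix (n >= 2 rows).
#' @return An object of class \code{plantar_normalizer} with \code{mean}
#'   and \code{sd} vectors.
#' @export
fit_normalizer <- function(x_train) {
  stopifnot(nrow(x_train) >= 2)
  if (any(!is.finite(x_train)))
    stop_plantar("non-finite values in feature matrix", "validation_error")
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  if (any(sd == 0)) {
    warning(sprintf("%d constant feature(s); sigma set to 1", sum(sd == 0)))
    sd[sd == 0] <- 1
  }
  structure(list(mean = mu, sd = sd), class = "plantar_normalizer")
}

#' @param object a \code{plantar_normalizer}.
#' @param newdata feature matrix over the same columns.
#' @param ... ignored.
#' @rdname fit_normalizer
#' @export
predict.plantar_normalizer <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(names(object$mean)))
    newdata <- newdata[, names(object$mean), drop = FALSE]
  sweep(sweep(newdata, 2, object$mean), 2, object$sd, "/")
}

#' Rule-based feature exclusion
#'
#' Drops features whose names match any of the glob patterns. The default
#' removes the minimum-pressure-gradient family (per-sensor values and
#' their symmetry indices), whose sign conventions make them biomechanically
#' unreasonable predictors; 132 of the 156 canonical features survive.
#'
#' @param names character vector of feature names.
#' @param patterns glob patterns to exclude.
#' @return Surviving names, in the original order.
#' @export
rule_exclude <- function(names, patterns = c("*_minPG", "*_minPG_SI")) {
  if (length(patterns) == 0) return(names)
  drop <- Reduce(`|`, lapply(patterns, function(p)
    grepl(utils::glob2rx(p), names)))
  names[!drop]
}

#' Pearson-correlation pruning
#'
#' Greedy redundancy removal: among feature pairs with |r| above
#' \code{r_max}, the pair with the largest |r| is resolved first by
#' dropping the member with the larger mean absolute correlation to all
#' remaining features (ties drop the later name in canonical order); the
#' correlation structure is re-evaluated after each drop. The survivors
#' have all pairwise |r| <= \code{r_max}.
#'
#' @param z_train standardized training matrix (named columns).
#' @param names feature names to consider (default: all columns).
#' @param r_max correlation threshold.
#' @return A list of class \code{prune_result}: \code{kept} (names),
#'   \code{log} (data frame of kept/dropped/r per resolved pair).
#' @export
correlation_prune <- function(z_train, names = colnames(z_train),
                              r_max = 0.8) {
  stopifnot(nrow(z_train) >= 3)
  z <- z_train[, names, drop = FALSE]
  keep <- names
  log <- list()
  repeat {
    cm <- abs(suppressWarnings(stats::cor(z[, keep, drop = FALSE])))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    if (max(cm) <= r_max) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    ma <- mean(cm[a, setdiff(keep, a)])
    mb <- mean(cm[b, setdiff(keep, b)])
    drop <- if (ma > mb) a
            else if (mb > ma) b
            else c(a, b)[which.max(match(c(a, b), names))]
    kept1 <- setdiff(c(a, b), drop)
    log[[length(log) + 1]] <- data.frame(kept = kept1, dropped = drop,
                                         r = max(cm))
    keep <- setdiff(keep, drop)
  }
  structure(list(kept = keep,
                 log = if (length(log)) do.call(rbind, log)
                       else data.frame(kept = character(), dropped = character(),
                                       r = numeric())),
            class = "prune_result")
}

#' LASSO feature selection
#'
#' Fits the L1-regularised linear regression path on the labeled,
#' standardized training samples; the penalty is chosen by 5-fold
#' cross-validated mean squared error (folds shuffled under the seed), the
#' model is refit at that penalty, and the \code{k} features with the
#' largest absolute coefficients are selected. If fewer than \code{k}
#' coefficients are nonzero at the CV optimum, the penalty is relaxed down
#' the path until at least \code{k} are active.
#'
#' @param z_train standardized labeled training matrix (named columns).
#' @param y labels.
#' @param k target subset size.
#' @param n_folds cross-validation folds.
#' @param seed seed for fold shuffling.
#' @return An object of class \code{selection_result}: \code{selected}
#'   (names), \code{coefficients} (named, at the final penalty),
#'   \code{lambda} (chosen penalty), \code{cv} (the cv.glmnet object).
#' @export
lasso_select <- function(z_train, y, k = 10, n_folds = 5, seed = 1) {
  if (k > ncol(z_train))
    stop_plantar("k exceeds the number of available features",
                 "selection_error")
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), nrow(z_train)))
  cv <- glmnet::cv.glmnet(z_train, y, alpha = 1, foldid = foldid,
                          standardize = FALSE)
  lam <- cv$lambda.min
  co <- as.vector(stats::coef(cv$glmnet.fit, s = lam))[-1]
  names(co) <- colnames(z_train)
  if (sum(co != 0) < k) {
    for (l in cv$lambda[cv$lambda < lam]) {
      co_try <- as.vector(stats::coef(cv$glmnet.fit, s = l))[-1]
      if (sum(co_try != 0) >= k) {
        lam <- l; co <- stats::setNames(co_try, colnames(z_train)); break
      }
    }
    if (sum(co != 0) < k) {
      # path exhausted: refit near-unpenalised to rank all features
      lam <- min(cv$lambda) * 1e-3
      co <- as.vector(stats::coef(
        glmnet::glmnet(z_train, y, alpha = 1, lambda = lam,
                       standardize = FALSE)))[-1]
      names(co) <- colnames(z_train)
    }
  }
  selected <- names(sort(abs(co), decreasing = TRUE))[seq_len(k)]
  structure(list(selected = selected,
                 coefficients = co,
                 lambda = lam,
                 cv = cv),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features at lambda = %.4g:\n  %s\n",
              length(x$selected), x$lambda,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Two-step feature selection
#'
#' Convenience wrapper: rule exclusion, correlation pruning at
#' \code{r_max}, then LASSO selection of \code{k} features, all on the
#' standardized labeled training data.
#'
#' @inheritParams lasso_select
#' @inheritParams correlation_prune
#' @param exclude_patterns passed to \code{\link{rule_exclude}}.
#' @return A \code{selection_result} with extra elements \code{excluded},
#'   \code{prune} (the \code{prune_result}).
#' @export
select_features <- function(z_train, y, k = 10, r_max = 0.8,
                            exclude_patterns = c("*_minPG", "*_minPG_SI"),
                            n_folds = 5, seed = 1) {
  surv <- rule_exclude(colnames(z_train), exclude_patterns)
  pr <- correlation_prune(z_train, surv, r_max = r_max)
  sel <- lasso_select(z_train[, pr$kept, drop = FALSE], y, k = k,
                      n_folds = n_folds, seed = seed)
  sel$excluded <- setdiff(colnames(z_train), surv)
  sel$prune <- pr
  sel
}
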