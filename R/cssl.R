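#' Composite supervised + consistency loss
#'
#' The training objective is
#' \deqn{L = \frac{1}{N_l}\sum_i (f(x_i) - y_i)^2 +
#'       \lambda_u \frac{1}{N_u}\sum_j (f(x_j) - f(x_j + \delta_j))^2}
#' where f is affine, the first sum runs over the labeled samples and the
#' second over unlabeled samples perturbed by zero-mean Gaussian draws
#' \eqn{\delta_j}. For an affine f the consistency term reduces to
#' \eqn{(w \cdot \delta_j)^2}, with expectation
#' \eqn{\sigma_\delta^2 \lVert w \rVert^2}.
#'
#' @param w weight vector.
#' @param b bias.
#' @param x_l labeled design matrix (N_l x d).
#' @param y_l labels.
#' @param x_u unlabeled design matrix (may have 0 rows).
#' @param delta perturbation matrix, same shape as \code{x_u}.
#' @param lambda_u consistency weight.
#' @return Named numeric vector \code{c(total, supervised, consistency)}.
#' @export
composite_loss <- function(w, b, x_l, y_l, x_u = NULL, delta = NULL,
                           lambda_u = 1) {
  r <- as.vector(x_l %*% w) + b - y_l
  sup <- mean(r^2)
  con <- if (is.null(x_u) || nrow(x_u) == 0) 0
         else mean(as.vector(delta %*% w)^2)
  c(total = sup + lambda_u * con, supervised = sup, consistency = con)
}

#' Consistency-regularized semi-supervised linear regression
#'
#' Fits an affine predictor of the Berg Balance Scale score by full-batch
#' gradient descent on the composite loss of \code{\link{composite_loss}}:
#' a mean-squared supervised term over the labeled samples plus
#' \code{lambda_u} times a consistency term that penalises prediction
#' change under small Gaussian input perturbations of the unlabeled
#' samples. Perturbations are redrawn every iteration from a seeded
#' stream; training stops at \code{max_iter} iterations or when the
#' relative change of the total loss falls below \code{tol}.
#'
#' Inputs are expected in standardized feature units. When a
#' \code{normalizer} (from \code{\link{fit_normalizer}}) is supplied, raw
#' feature matrices are standardized internally, and \code{predict} applies
#' the same transform to new data.
#'
#' @param x_l labeled feature matrix (rows = samples).
#' @param y_l BBS labels in [0, 56].
#' @param x_u unlabeled feature matrix (NULL for purely supervised).
#' @param lambda_u consistency weight (>= 0).
#' @param sigma_delta perturbation standard deviation, in standardized
#'   feature units.
#' @param learning_rate gradient-descent step size.
#' @param max_iter iteration budget.
#' @param tol relative total-loss change convergence tolerance.
#' @param seed seed for the perturbation stream.
#' @param normalizer optional \code{plantar_normalizer} applied to inputs.
#' @param clamp if TRUE (default), predictions are clamped to [0, 56].
#' @return An object of class \code{cssl}: weights \code{w}, bias \code{b},
#'   \code{history} (per-iteration total/supervised/consistency loss),
#'   \code{config}, \code{normalizer}, \code{feature_names}, plus the
#'   training data fits needed by \code{residuals}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' y <- x %*% c(3, -2, 1, 0) + 28
#' fit <- cssl(x, y, lambda_u = 0, max_iter = 2000)
#' coef(fit)
#' @export
cssl <- function(x_l, y_l, x_u = NULL,
                 lambda_u = 1.0, sigma_delta = 0.1,
                 learning_rate = 1e-2, max_iter = 5000, tol = 1e-8,
                 seed = 1, normalizer = NULL, clamp = TRUE) {
  stopifnot(lambda_u >= 0, sigma_delta >= 0)
  x_l <- as.matrix(x_l)
  y_l <- as.numeric(y_l)
  stopifnot(nrow(x_l) == length(y_l))
  if (!is.null(x_u)) x_u <- as.matrix(x_u)
  if (!is.null(normalizer)) {
    x_l <- predict(normalizer, x_l)
    if (!is.null(x_u)) x_u <- predict(normalizer, x_u)
  }
  d <- ncol(x_l)
  n_l <- nrow(x_l)
  n_u <- if (is.null(x_u)) 0 else nrow(x_u)
  use_u <- n_u > 0 && lambda_u > 0 && sigma_delta > 0

  set.seed(seed)
  w <- rep(0, d)
  b <- 0
  hist <- matrix(NA_real_, max_iter, 3,
                 dimnames = list(NULL, c("total", "supervised", "consistency")))
  prev <- Inf
  it <- 0
  for (it in seq_len(max_iter)) {
    r <- as.vector(x_l %*% w) + b - y_l
    gw <- 2 * crossprod(x_l, r)[, 1] / n_l
    gb <- 2 * sum(r) / n_l
    sup <- mean(r^2)
    con <- 0
    if (use_u) {
      delta <- matrix(stats::rnorm(n_u * d, 0, sigma_delta), n_u, d)
      dw <- as.vector(delta %*% w)
      con <- mean(dw^2)
      gw <- gw + lambda_u * 2 * crossprod(delta, dw)[, 1] / n_u
    }
    total <- sup + lambda_u * con
    if (!is.finite(total))
      stop_plantar("training diverged; reduce the learning rate",
                   "training_error")
    hist[it, ] <- c(total, sup, con)
    w <- w - learning_rate * gw
    b <- b - learning_rate * gb
    if (is.finite(prev) && abs(prev - total) < tol * max(prev, 1e-12)) break
    prev <- total
  }
  hist <- hist[seq_len(it), , drop = FALSE]

  fitted_std <- as.vector(x_l %*% w) + b
  structure(list(w = stats::setNames(as.vector(w),
                                     colnames(x_l) %||% NULL),
                 b = b,
                 history = hist,
                 iterations = it,
                 config = list(lambda_u = lambda_u, sigma_delta = sigma_delta,
                               learning_rate = learning_rate,
                               max_iter = max_iter, tol = tol, seed = seed,
                               clamp = clamp),
                 normalizer = normalizer,
                 feature_names = colnames(x_l),
                 n_labeled = n_l, n_unlabeled = n_u,
                 y = y_l, fitted_std = fitted_std),
            class = "cssl")
}

#' @export
print.cssl <- function(x, ...) {
  cat(sprintf("<cssl> consistency-regularized linear regression (lambda_u = %g, sigma_delta = %g)\n",
              x$config$lambda_u, x$config$sigma_delta))
  cat(sprintf("  %d labeled + %d unlabeled samples, %d features, %d iterations\n",
              x$n_labeled, x$n_unlabeled, length(x$w), x$iterations))
  cat(sprintf("  final loss: total %.4f (supervised %.4f, consistency %.4f)\n",
              x$history[nrow(x$history), 1], x$history[nrow(x$history), 2],
              x$history[nrow(x$history), 3]))
  invisible(x)
}

#' @export
coef.cssl <- function(object, ...) {
  c("(bias)" = object$b, object$w)
}

#' Predict BBS scores
#'
#' @param object a fitted \code{cssl} model.
#' @param newdata feature matrix; raw scale if the model carries a
#'   normalizer, standardized otherwise.
#' @param clamp clamp predictions to the BBS range [0, 56]; defaults to the
#'   model's training-time setting.
#' @param ... ignored.
#' @return Numeric vector of predicted scores.
#' @export
predict.cssl <- function(object, newdata, clamp = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$normalizer))
    newdata <- predict(object$normalizer, newdata)
  else if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    if (!all(object$feature_names %in% colnames(newdata)))
      stop_plantar("newdata is missing model features", "feature_error")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  p <- as.vector(newdata %*% object$w) + object$b
  clamp <- clamp %||% object$config$clamp
  if (clamp) p <- pmin(56, pmax(0, p))
  p
}

#' @export
fitted.cssl <- function(object, ...) {
  p <- object$fitted_std
  if (object$config$clamp) p <- pmin(56, pmax(0, p)) else p
}

#' @export
residuals.cssl <- function(object, ...) {
  object$y - object$fitted_std
}

#' @export
summary.cssl <- function(object, ...) {
  res <- residuals(object)
  out <- list(model = object,
              coefficients = coef(object),
              train = evaluate(object$y, object$fitted_std),
              sigma = stats::sd(res))
  class(out) <- "summary.cssl"
  out
}

#' @export
print.summary.cssl <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients (standardized features):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nTraining fit: RMSE %.3f, MAE %.3f, R2 %.4f\n",
              x$train$rmse, x$train$mae, x$train$r2))
  invisible(x)
}

#' Plot the training loss history
#'
#' Total, supervised and consistency loss per iteration on a log-x axis.
#'
#' @param x a fitted \code{cssl}.
#' @param ... passed to \code{matplot}.
#' @export
plot.cssl <- function(x, ...) {
  h <- x$history
  graphics::matplot(seq_len(nrow(h)), h, type = "l", lty = c(1, 2, 3),
                    col = c("black", "steelblue", "firebrick"),
                    xlab = "iteration", ylab = "loss", log = "x", ...)
  graphics::legend("topright", colnames(h), lty = c(1, 2, 3),
                   col = c("black", "steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Simulate responses from the fitted model
#'
#' Draws \code{nsim} response vectors at the training inputs: fitted values
#' plus Gaussian noise with the residual standard deviation.
#'
#' @param object a fitted \code{cssl}.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... ignored.
#' @return A data frame with \code{nsim} columns.
#' @export
simulate.cssl <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted_std
  s <- stats::sd(residuals(object))
  as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, s)))
}

#' Regression evaluation metrics
#'
#' @param y_true observed scores.
#' @param y_pred predicted scores.
#' @return A list of class \code{eval_report}: \code{rmse}, \code{mae},
#'   \code{r2} (NA when \code{y_true} has zero variance).
#' @examples
#' evaluate(c(0, 10), c(2, 8))  # RMSE 2, MAE 2, R2 0.84
#' @export
evaluate <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  e <- y_true - y_pred
  sst <- sum((y_true - mean(y_true))^2)
  structure(list(rmse = sqrt(mean(e^2)),
                 mae = mean(abs(e)),
                 r2 = if (sst == 0) NA_real_ else 1 - sum(e^2) / sst),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("RMSE %.3f  MAE %.3f  R2 %s\n", x$rmse, x$mae,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2)))
  invisible(x)
}
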