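#' Recursive least-squares general linear model
#'
#' Fits the GLM `y = X beta + e` incrementally, one sample at a time, to
#' any number of channels at once. After an initial batch solve on the
#' first full-rank prefix of the design, the inverse Gram matrix
#' `P = (X'X)^-1` and the per-channel coefficient vectors are advanced
#' by rank-1 recursions:
#' \deqn{\beta_{t+1} = \beta_t + \frac{P_t x_{t+1} (y_{t+1} - x_{t+1}'\beta_t)}
#'       {1 + x_{t+1}' P_t x_{t+1}}}
#' \deqn{P_{t+1} = P_t - \frac{P_t x_{t+1} x_{t+1}' P_t}
#'       {1 + x_{t+1}' P_t x_{t+1}}}
#' `P` is shared by all channels, so the per-sample cost is
#' `O(p^2 + n_channels * p)`, independent of how many samples have been
#' seen. At every sample the coefficients equal the batch
#' ordinary-least-squares solution on all rows so far (up to floating
#' point); as numerical insurance, `P` is refreshed by a direct solve
#' every `refresh_every` updates if its drift against the true inverse
#' Gram exceeds `drift_tol`.
#'
#' Coefficients are emitted only from the first full-rank sample on;
#' before that the model is uninitialized.
#'
#' @param X design matrix (samples x predictors), e.g. [build_design()].
#' @param Y response matrix (samples x channels) or vector.
#' @param record if `TRUE`, keep the full coefficient trajectory
#'   (`predictors x channels x samples` array, `NA` before
#'   initialization).
#' @param refresh_every interval (in updates) of the drift check.
#' @param drift_tol relative drift of `P` that triggers a refresh.
#' @param condition_max largest acceptable condition number of the Gram
#'   matrix at initialization.
#' @return an object of class `"rlsglm"` with methods [coef()],
#'   [print()], [summary()], [predict()], [residuals()], [update()]
#'   (streaming update) and [plot()].
#' @examples
#' p <- protocol(2, list(task = rbind(c(10, 20), c(40, 50))), 60)
#' X <- build_design(p)
#' y <- X %*% c(1.5, 0.2) + rnorm(nrow(X), sd = 0.1)
#' fit <- rlsglm(X, y)
#' coef(fit)
#' @export
rlsglm <- function(X, Y, record = FALSE, refresh_every = 1000L,
                   drift_tol = 1e-8, condition_max = 1e10) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  p <- ncol(X)
  fit <- structure(
    list(
      p = p, n_channels = ncol(Y), t = 0L, initialized_at = NA_integer_,
      P = NULL, G = NULL, coefficients = NULL, rss = numeric(ncol(Y)),
      predictor_names = colnames(X), ops = numeric(0),
      refresh_every = as.integer(refresh_every), drift_tol = drift_tol,
      condition_max = condition_max, updates_since_refresh = 0L,
      X = matrix(numeric(0), 0L, p), Y = matrix(numeric(0), 0L, ncol(Y)),
      trajectory = if (record) array(NA_real_, c(p, ncol(Y), 0L)),
      skipped = matrix(FALSE, 0L, ncol(Y))
    ),
    class = "rlsglm"
  )
  update(fit, X, Y)
}

#' Streaming update of a recursive least-squares GLM
#'
#' Feeds one or more new samples into a fitted (or still-uninitialized)
#' [rlsglm()] state. Non-finite responses cause the affected channel to
#' be skipped (flagged) for that sample; its coefficients keep their
#' previous value.
#'
#' @param object an `"rlsglm"` object.
#' @param x_new new design row(s): vector of length `p` or matrix.
#' @param y_new new response(s): vector of length `n_channels` or matrix.
#' @param ... unused.
#' @return the advanced `"rlsglm"` object.
#' @export
update.rlsglm <- function(object, x_new, y_new, ...) {
  p <- object$p
  X <- matrix(as.numeric(x_new), ncol = p)
  Y <- matrix(as.numeric(y_new), ncol = object$n_channels)
  if (nrow(X) != nrow(Y)) stop("x_new and y_new row counts differ")
  record <- !is.null(object$trajectory)
  if (record && nrow(X)) {
    object$trajectory <- array(
      c(object$trajectory, rep(NA_real_, p * object$n_channels * nrow(X))),
      dim = c(p, object$n_channels, dim(object$trajectory)[3L] + nrow(X))
    )
  }
  object$X <- rbind(object$X, X)
  object$Y <- rbind(object$Y, Y)
  object$skipped <- rbind(object$skipped, !is.finite(Y))
  ops <- numeric(nrow(X)) # multiply-accumulate count of each per-sample update
  for (i in seq_len(nrow(X))) {
    object$t <- object$t + 1L
    t_now <- object$t
    if (is.na(object$initialized_at)) {
      if (t_now >= p) { # try a batch initialization on the full prefix
        Xp <- object$X[seq_len(t_now), , drop = FALSE]
        G <- crossprod(Xp)
        if (qr(Xp)$rank == p && kappa(G, exact = TRUE) < object$condition_max) {
          object$P <- solve(G)
          object$G <- G
          Yp <- object$Y[seq_len(t_now), , drop = FALSE]
          Yp[!is.finite(Yp)] <- 0 # skipped samples contribute zero
          object$coefficients <- object$P %*% crossprod(Xp, Yp)
          res <- Yp - Xp %*% object$coefficients
          object$rss <- colSums(res^2)
          object$initialized_at <- t_now
        }
      }
    } else {
      x <- X[i, ]
      y <- Y[i, ]
      Px <- object$P %*% x
      denom <- 1 + sum(x * Px)
      err <- y - drop(crossprod(x, object$coefficients))
      live <- is.finite(err)
      err[!live] <- 0
      object$coefficients <- object$coefficients + (Px %*% rbind(err)) / denom
      object$rss <- object$rss + err^2 / denom
      object$P <- object$P - tcrossprod(Px) / denom
      object$G <- object$G + tcrossprod(x) # maintained for the drift check
      # sizes of the operands actually touched this sample: fixed in t
      ops[i] <- 3 * p^2 + 2 * p + length(err) * (p + 2)
      object$updates_since_refresh <- object$updates_since_refresh + 1L
      if (object$updates_since_refresh >= object$refresh_every) {
        Pd <- solve(object$G)
        if (max(abs(object$P - Pd)) > object$drift_tol * (1 + max(abs(Pd)))) {
          object$P <- Pd
        }
        object$updates_since_refresh <- 0L
      }
    }
    if (record && !is.na(object$initialized_at)) {
      object$trajectory[, , t_now] <- object$coefficients
    }
  }
  object$ops <- c(object$ops, ops)
  object
}

#' @export
coef.rlsglm <- function(object, ...) {
  if (is.na(object$initialized_at)) {
    return(matrix(NA_real_, object$p, object$n_channels,
                  dimnames = list(object$predictor_names, NULL)))
  }
  structure(object$coefficients,
            dimnames = list(object$predictor_names, NULL))
}

#' @export
print.rlsglm <- function(x, ...) {
  cat(sprintf(
    "recursive least-squares GLM: %d predictor(s), %d channel(s), %d sample(s)\n",
    x$p, x$n_channels, x$t
  ))
  if (is.na(x$initialized_at)) {
    cat("  not yet initialized (design not full rank)\n")
  } else {
    cat(sprintf("  initialized at sample %d\n", x$initialized_at))
  }
  invisible(x)
}

#' Summary of a recursive least-squares GLM
#'
#' Reports per-channel coefficients and t-values. The t-values are
#' computed under the ordinary independence assumption and are labeled
#' autocorrelation-naive: fNIRS sampling rates induce strong serial
#' correlation, so betas (and contrasts of betas) are the recommended
#' quantities for judgments.
#'
#' @param object an `"rlsglm"` object.
#' @param ... unused.
#' @export
summary.rlsglm <- function(object, ...) {
  beta <- coef(object)
  df <- object$t - object$p
  sigma2 <- if (df > 0) object$rss / df else rep(NA_real_, object$n_channels)
  se <- if (!is.na(object$initialized_at)) {
    sqrt(outer(diag(object$P), sigma2))
  } else {
    beta * NA_real_
  }
  out <- list(
    coefficients = beta, se = se, t_naive = beta / se, df = df,
    n_samples = object$t, n_channels = object$n_channels
  )
  class(out) <- "summary.rlsglm"
  out
}

#' @export
print.summary.rlsglm <- function(x, ...) {
  cat(sprintf(
    "rlsGLM summary: %d sample(s), %d channel(s), residual df %d\n",
    x$n_samples, x$n_channels, x$df
  ))
  cat("coefficients (channels in columns):\n")
  print(round(x$coefficients, 6))
  cat("autocorrelation-naive t values:\n")
  print(round(x$t_naive, 3))
  invisible(x)
}

#' @export
predict.rlsglm <- function(object, newdata = NULL, ...) {
  beta <- coef(object)
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  X %*% beta
}

#' @export
residuals.rlsglm <- function(object, ...) {
  object$Y - predict(object)
}

#' @export
fitted.rlsglm <- function(object, ...) predict(object)

#' Plot the coefficient trajectory of a recursive least-squares GLM
#'
#' Requires a fit with `record = TRUE`.
#'
#' @param x an `"rlsglm"` object.
#' @param channel channel to plot.
#' @param ... passed to [matplot()].
#' @export
plot.rlsglm <- function(x, channel = 1L, ...) {
  if (is.null(x$trajectory)) stop("fit with record = TRUE to plot trajectories")
  tr <- t(x$trajectory[, channel, ])
  graphics::matplot(tr, type = "l", lty = 1,
                    xlab = "sample", ylab = "beta",
                    main = sprintf("rlsGLM coefficients, channel %d", channel), ...)
  graphics::legend("topright", legend = x$predictor_names,
                   col = seq_len(x$p), lty = 1, bty = "n")
  invisible(x)
}

#' Contrast value of a fitted GLM
#'
#' Evaluates `c' beta` per channel for a contrast vector `c` over the
#' predictors (confounds weighted 0).
#'
#' @param object a fitted [rlsglm()].
#' @param contrast numeric weight vector of length `p`, or a named
#'   vector over a subset of predictor names (others 0).
#' @param channels channel indices (default all).
#' @return numeric vector of contrast values, one per channel.
#' @export
contrast_value <- function(object, contrast, channels = seq_len(object$n_channels)) {
  if (is.na(object$initialized_at)) stop("model not initialized")
  if (!is.null(names(contrast))) {
    w <- setNames(numeric(object$p), object$predictor_names)
    unknown <- setdiff(names(contrast), object$predictor_names)
    if (length(unknown)) stop("unknown predictor(s): ", paste(unknown, collapse = ", "))
    w[names(contrast)] <- contrast
    contrast <- w
  }
  if (length(contrast) != object$p) stop("contrast length must equal the predictor count")
  if (all(contrast == 0)) stop("contrast must have a nonzero weight")
  drop(crossprod(contrast, coef(object)[, channels, drop = FALSE]))
}

#' Batch ordinary-least-squares reference fit
#'
#' Direct closed-form solve `beta = (X'X)^-1 X'y` on a full design, used
#' as the offline reference against which the incremental estimates are
#' compared.
#'
#' @param X design matrix.
#' @param Y response matrix or vector.
#' @return coefficient matrix (predictors x channels).
#' @export
batch_ols <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  fit <- qr.coef(qr(X), Y)
  rownames(fit) <- colnames(X)
  fit
}
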