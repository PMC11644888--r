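#' Score a fatigue self-assessment (FSAS) form
#'
#' The questionnaire has 10 statements, each answered on a 5-point frequency
#' scale (Never = 1 ... Always = 5). The total is the plain sum of the 10
#' responses, ranging from 10 (least fatigued) to 50 (most fatigued). By
#' default every item is scored in the same direction; `reverse_items`
#' optionally reverse-scores the positively worded items 4 and 10
#' (`6 - response`), the usual psychometric convention.
#'
#' @param responses An integer vector of length 10 (one form), or a data
#'   frame / matrix with 10 columns (one form per row), values in 1-5.
#' @param reverse_items Reverse-score items 4 and 10 (default `FALSE`).
#' @return Numeric total(s) in `[10, 50]`.
#' @examples
#' score_fsas(rep(1, 10)) # 10
#' score_fsas(rep(5, 10)) # 50
#' @export
score_fsas <- function(responses, reverse_items = FALSE) {
  m <- if (is.data.frame(responses) || is.matrix(responses)) {
    as.matrix(responses)
  } else {
    matrix(responses, nrow = 1)
  }
  if (ncol(m) != 10) abort("an FSAS form has exactly 10 responses.")
  if (!is.numeric(m) || anyNA(m) || any(m != round(m)) ||
    any(m < 1) || any(m > 5)) {
    abort("responses must be integers in 1..5.")
  }
  if (reverse_items) m[, c(4, 10)] <- 6 - m[, c(4, 10)]
  unname(rowSums(m))
}

#' Relative-error accuracy of fatigue predictions
#'
#' `r = (1 - mean(|pred - truth| / truth)) * 100`, i.e. 100% minus the mean
#' absolute relative error in percent. `signed = TRUE` drops the absolute
#' value, letting over- and under-predictions cancel (kept as a documented
#' variant; the absolute form is the default because the quantity is used
#' as an accuracy).
#'
#' The measure is invariant to rescaling predictions and truths by a common
#' positive constant, and may be negative for very poor predictors.
#'
#' @param predicted,truth Equal-length numeric vectors; `truth` must be
#'   positive.
#' @param signed Use the signed relative error (default `FALSE`).
#' @return Accuracy in percent.
#' @examples
#' fatigue_accuracy(11, 10) # 90
#' @export
fatigue_accuracy <- function(predicted, truth, signed = FALSE) {
  if (length(predicted) != length(truth) || length(truth) == 0) {
    abort("`predicted` and `truth` must have equal nonzero length.")
  }
  if (any(truth <= 0)) abort("`truth` must be positive.")
  err <- (predicted - truth) / truth
  if (!signed) err <- abs(err)
  (1 - mean(err)) * 100
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit the blink-feature fatigue network
#'
#' A classic fully connected feed-forward network with 3 inputs (mean eye
#' closing, opening, and idle time), one sigmoid hidden layer (5 neurons by
#' default), and one linear output neuron, trained by full-batch gradient
#' descent with momentum on the mean-squared error - plain backpropagation.
#' Features are z-scored internally and the target scale is mapped from
#' \[10, 50\] to \[0, 1\] for training.
#'
#' @param data Data frame with columns `closing_s`, `opening_s`, `idle_s`,
#'   `scale` (at least 10 rows; scale in \[10, 50\]).
#' @param hidden Hidden-layer width.
#' @param iterations Gradient-descent iterations (default 2000; the loss
#'   plateaus by roughly 1500 on datasets of this kind).
#' @param learning_rate Step size on the normalized loss.
#' @param momentum Classical momentum coefficient.
#' @param seed Optional seed for weight initialization.
#' @return A `fatigue_network` object with the weight matrices, the feature
#'   standardization parameters, and the loss trajectory. Methods:
#'   [predict.fatigue_network()], [tidy.fatigue_network()],
#'   [glance.fatigue_network()], [autoplot.fatigue_network()].
#' @examples
#' d <- generate_feature_dataset(200, noise_sd = 0, seed = 1)
#' net <- fit_fatigue_network(d, iterations = 500, seed = 1)
#' glance(net)
#' @export
fit_fatigue_network <- function(data, hidden = 5, iterations = 2000,
                                learning_rate = 0.5, momentum = 0.9,
                                seed = NULL) {
  cols <- c("closing_s", "opening_s", "idle_s")
  if (!is.data.frame(data) || !all(c(cols, "scale") %in% names(data))) {
    abort("`data` needs columns closing_s, opening_s, idle_s, scale.")
  }
  if (nrow(data) < 10) abort("need at least 10 training samples.")
  check_number(iterations, "iterations", lower = 1)
  X <- as.matrix(data[cols])
  y01 <- (data$scale - 10) / 40
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (any(sdev == 0)) {
    warn("constant feature(s); standardization keeps them at zero.")
    sdev[sdev == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  n <- nrow(Xs)
  p <- length(cols)
  with_optional_seed(seed, {
    W1 <- matrix(runif(p * hidden, -0.5, 0.5) / sqrt(p), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(runif(hidden, -0.5, 0.5) / sqrt(hidden), hidden, 1)
    b2 <- 0
    vW1 <- W1 * 0
    vb1 <- b1
    vW2 <- W2 * 0
    vb2 <- 0
    loss <- numeric(iterations)
    for (it in seq_len(iterations)) {
      H <- sigmoid(sweep(Xs %*% W1, 2, b1, "+"))
      e <- drop(H %*% W2) + b2 - y01
      loss[it] <- mean(e^2)
      gy <- 2 * e / n
      gW2 <- crossprod(H, gy)
      gb2 <- sum(gy)
      gZ <- outer(gy, drop(W2)) * H * (1 - H)
      gW1 <- crossprod(Xs, gZ)
      gb1 <- colSums(gZ)
      vW1 <- momentum * vW1 - learning_rate * gW1
      vb1 <- momentum * vb1 - learning_rate * gb1
      vW2 <- momentum * vW2 - learning_rate * gW2
      vb2 <- momentum * vb2 - learning_rate * gb2
      W1 <- W1 + vW1
      b1 <- b1 + vb1
      W2 <- W2 + vW2
      b2 <- b2 + vb2
    }
    structure(list(
      W1 = W1, b1 = b1, W2 = W2, b2 = b2, feature_mean = mu,
      feature_sd = sdev, loss = loss, hidden = hidden,
      iterations = iterations, learning_rate = learning_rate,
      momentum = momentum, n_train = n, seed = seed
    ), class = "fatigue_network")
  })
}

#' Predict fatigue scale from blink features
#'
#' Forward pass through the trained network; the output is clamped to the
#' FSAS range \[10, 50\].
#'
#' @param object A [fit_fatigue_network()] fit.
#' @param newdata Data frame with columns `closing_s`, `opening_s`,
#'   `idle_s`.
#' @param ... Unused.
#' @return Numeric predictions in `[10, 50]`.
#' @export
predict.fatigue_network <- function(object, newdata, ...) {
  cols <- c("closing_s", "opening_s", "idle_s")
  if (!is.data.frame(newdata) || !all(cols %in% names(newdata))) {
    abort("`newdata` needs columns closing_s, opening_s, idle_s.")
  }
  X <- as.matrix(newdata[cols])
  Xs <- sweep(sweep(X, 2, object$feature_mean), 2, object$feature_sd, "/")
  H <- sigmoid(sweep(Xs %*% object$W1, 2, object$b1, "+"))
  y01 <- drop(H %*% object$W2) + object$b2
  pmin(pmax(y01, 0), 1) * 40 + 10
}

#' @describeIn fit_fatigue_network One row per network weight
#'   (`layer`, `from`, `to`, `estimate`).
#' @param x A `fatigue_network` object.
#' @method tidy fatigue_network
#' @export
tidy.fatigue_network <- function(x, ...) {
  feats <- c("closing_s", "opening_s", "idle_s")
  hid <- paste0("h", seq_len(x$hidden))
  dplyr::bind_rows(
    tibble::tibble(
      layer = "hidden",
      from = rep(c(feats, "bias"), times = x$hidden),
      to = rep(hid, each = length(feats) + 1),
      estimate = as.vector(rbind(x$W1, x$b1))
    ),
    tibble::tibble(
      layer = "output", from = c(hid, "bias"), to = "scale",
      estimate = c(drop(x$W2), x$b2)
    )
  )
}

#' @describeIn fit_fatigue_network One-row training summary.
#' @method glance fatigue_network
#' @export
glance.fatigue_network <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train, hidden = x$hidden, iterations = x$iterations,
    learning_rate = x$learning_rate, momentum = x$momentum,
    final_loss = x$loss[length(x$loss)]
  )
}

#' @export
print.fatigue_network <- function(x, ...) {
  cat(sprintf(
    "<fatigue_network> 3-%d-1, %d iterations on %d samples, final loss %.3g\n",
    x$hidden, x$iterations, x$n_train, x$loss[length(x$loss)]
  ))
  invisible(x)
}

#' Train/test evaluation of the fatigue network
#'
#' Shuffles the samples with a seeded random permutation, trains on
#' `train_fraction` of them, and reports the relative-error accuracy on the
#' hold-out.
#'
#' @param data Labelled feature data as for [fit_fatigue_network()].
#' @param train_fraction Fraction used for training (default 0.8).
#' @param seed Optional seed covering both the split and the weight
#'   initialization.
#' @param ... Passed on to [fit_fatigue_network()].
#' @return A list with `network`, `accuracy` (percent, on the hold-out),
#'   `n_train`, `n_test`, and the `test` tibble with a `.pred` column.
#' @export
evaluate_fatigue <- function(data, train_fraction = 0.8, seed = NULL, ...) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must be in (0, 1).")
  }
  seeds <- if (is.null(seed)) c(NULL, NULL) else derive_seeds(seed, 2)
  idx <- with_optional_seed(seeds[1], sample(nrow(data)))
  ntr <- floor(train_fraction * nrow(data))
  train <- data[idx[seq_len(ntr)], ]
  test <- data[idx[-seq_len(ntr)], ]
  net <- fit_fatigue_network(train, seed = seeds[2], ...)
  pred <- predict(net, test)
  test$.pred <- pred
  list(
    network = net,
    accuracy = fatigue_accuracy(pred, test$scale),
    n_train = ntr, n_test = nrow(test), test = tibble::as_tibble(test)
  )
}
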