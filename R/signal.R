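#' Multichannel signal matrix
#'
#' Wraps an n_channels x n_samples numeric matrix of observed signals
#' (rows = channels, columns = time samples).
#'
#' @param data numeric matrix, channels in rows.
#' @param centered logical; whether rows are known to be zero-mean.
#' @return An object of class \code{"signal_matrix"}.
#' @export
signal_matrix <- function(data, centered = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("signal matrix must be finite")
  if (ncol(data) <= nrow(data))
    stop("need more samples than channels (rows = channels, columns = samples)")
  structure(list(data = data, centered = centered), class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d channels x %d samples (%scentered)\n",
              nrow(x$data), ncol(x$data), if (x$centered) "" else "not "))
  invisible(x)
}

.as_signal <- function(x) {
  if (inherits(x, "signal_matrix")) x else signal_matrix(x)
}

#' Center the observed signals
#'
#' Removes the mean of each channel. The original means are retained as
#' the \code{"means"} attribute so the operation is invertible.
#'
#' @param x a \code{\link{signal_matrix}} or plain matrix.
#' @return A centered \code{signal_matrix}.
#' @export
center_signals <- function(x) {
  x <- .as_signal(x)
  m <- rowMeans(x$data)
  out <- signal_matrix(x$data - m, centered = TRUE)
  attr(out, "means") <- m
  out
}

#' Whiten the observed signals
#'
#' PCA sphering: eigendecomposition of the sample covariance of the
#' centered input; components whose eigenvalue falls below
#' \code{rank_tol} times the largest are dropped. The whitened output has
#' identity sample covariance on the retained rank.
#'
#' @param x a centered \code{\link{signal_matrix}}.
#' @param rank_tol relative eigenvalue cutoff (default 1e-10).
#' @return A list with the whitened \code{signals} (class
#'   \code{signal_matrix}, k x n_samples) and the \code{model}, an object of
#'   class \code{"whitening_model"} holding \code{mean}, \code{sphering}
#'   (k x n), \code{desphering} (n x k), \code{retained_rank} and
#'   \code{eigenvalues}.
#' @export
whiten_signals <- function(x, rank_tol = 1e-10) {
  x <- .as_signal(x)
  m <- if (x$centered) rep(0, nrow(x$data)) else rowMeans(x$data)
  xc <- x$data - m
  C <- tcrossprod(xc) / ncol(xc)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values >= rank_tol * max(e$values)
  if (max(e$values) <= 0 || !any(keep)) stop("degenerate input: no retained components")
  k <- sum(keep)
  Ek <- e$vectors[, seq_len(k), drop = FALSE]
  dk <- e$values[seq_len(k)]
  V <- (1 / sqrt(dk)) * t(Ek)          # k x n sphering
  W <- Ek * rep(sqrt(dk), each = nrow(Ek))  # n x k desphering
  model <- structure(list(mean = m, sphering = V, desphering = W,
                          retained_rank = k, eigenvalues = e$values),
                     class = "whitening_model")
  z <- signal_matrix(V %*% xc, centered = TRUE)
  attr(z, "whitening") <- model
  list(signals = z, model = model)
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf("whitening_model: rank %d of %d channels\n",
              x$retained_rank, length(x$mean)))
  invisible(x)
}

#' Normalized reference signal
#'
#' Centers and scales a trace to zero mean, unit variance.
#'
#' @param trace numeric vector.
#' @return An object of class \code{"reference_signal"} (a normalized
#'   numeric vector with attribute \code{normalized = TRUE}).
#' @export
reference_signal <- function(trace) {
  trace <- as.numeric(trace)
  if (!all(is.finite(trace))) stop("reference must be finite")
  s <- stats::sd(trace)
  if (s < .Machine$double.eps * max(abs(trace), 1)) stop("zero-variance reference")
  r <- (trace - mean(trace)) / s
  # sd() uses the n-1 denominator; the closeness algebra assumes population
  # moments, so rescale to unit second moment about the mean.
  r <- r / sqrt(mean(r^2))
  structure(r, class = "reference_signal", normalized = TRUE)
}

#' @export
print.reference_signal <- function(x, ...) {
  cat(sprintf("reference_signal: %d samples, normalized\n", length(x)))
  invisible(x)
}

#' Use an observed channel directly as the reference
#'
#' When the desired component dominates one observed channel (e.g. the
#' fetal ECG visible in one abdominal lead, or an EEG channel badly
#' contaminated by the eye-blink artifact one wants to isolate), that
#' channel, normalized, is a ready-made reference.
#'
#' @param x a \code{\link{signal_matrix}} or matrix.
#' @param channel channel (row) index.
#' @return A \code{\link{reference_signal}}.
#' @export
channel_reference <- function(x, channel) {
  x <- .as_signal(x)
  if (channel < 1 || channel > nrow(x$data)) stop("invalid channel index")
  reference_signal(x$data[channel, ])
}

#' Closeness between an output candidate and the reference
#'
#' Both measures assume zero-mean, unit-variance inputs and are oriented so
#' that smaller means closer: \code{corr} is the negative correlation
#' -E{y r} (in [-1, 1]); \code{mse} is E{(y - r)^2} (in [0, 4]). For unit
#' variance signals the two are equivalent: mse = 2 (1 + corr).
#'
#' @param y numeric vector, zero mean and unit variance.
#' @param r a \code{\link{reference_signal}} (or normalized vector).
#' @param measure \code{"corr"} or \code{"mse"}.
#' @return Scalar closeness.
#' @export
closeness <- function(y, r, measure = c("corr", "mse")) {
  measure <- match.arg(measure)
  if (length(y) != length(r)) stop("length mismatch between output and reference")
  if (abs(mean(y)) > 1e-3 || abs(mean(y^2) - 1) > 5e-3)
    stop("closeness expects zero-mean, unit-variance y")
  if (measure == "corr") -mean(y * as.numeric(r)) else mean((y - as.numeric(r))^2)
}
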