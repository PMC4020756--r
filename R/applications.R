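#' Remove an extracted component from the reference
#'
#' Reference deflation: after an (undesired) component y has been
#' extracted, its contribution is regressed out of the reference,
#' r_new = r - E{r y} y, and the result renormalized. Re-running the
#' extractor with the deflated reference can no longer converge to y
#' (its correlation with the new reference is zero, hence infeasible for
#' any negative correlation threshold), so repeated deflation walks
#' through the components present in the reference.
#'
#' @param r normalized \code{\link{reference_signal}}.
#' @param y extracted source, zero mean and unit variance.
#' @return Deflated, renormalized \code{reference_signal}.
#' @export
deflate_reference <- function(r, y) {
  r <- as.numeric(r); y <- as.numeric(y)
  if (length(r) != length(y)) stop("length mismatch")
  res <- r - mean(r * y) * y
  if (sqrt(mean(res^2)) < 1e-8) stop("reference fully explained by extracted source")
  reference_signal(res)
}

#' Decorrelate a new component against previously extracted ones
#'
#' When underlying sources are not perfectly independent (or estimated
#' with error), deflating the reference by raw outputs can re-introduce
#' correlation with earlier components. This Gram-Schmidt step makes the
#' current component uncorrelated with every prior one before it is used
#' for deflation.
#'
#' @param y_new newly extracted source (zero mean, unit variance).
#' @param prior list (or matrix rows) of previously accepted sources.
#' @return Renormalized source uncorrelated with every prior source.
#' @export
reorthogonalize_ic <- function(y_new, prior = list()) {
  y <- as.numeric(y_new)
  if (is.matrix(prior)) prior <- split(prior, row(prior))
  for (p in prior) {
    p <- as.numeric(p)
    y <- y - mean(y * p) * p
  }
  if (sqrt(mean(y^2)) < 1e-8) stop("component lies in the span of prior components")
  as.numeric(reference_signal(y))
}

#' Constraint center of the inequality region
#'
#' The weight maximizing the correlation between w'z and the reference
#' under unit output variance is normalize(E{z r}); it is the point the
#' multiplier dynamics pull the learning towards when the iterate is
#' infeasible, and a good initial vector for application workflows.
#'
#' @param z whitened signals.
#' @param r normalized \code{\link{reference_signal}}.
#' @return Unit-norm weight vector.
#' @export
constraint_center <- function(z, r) {
  Z <- if (inherits(z, "signal_matrix")) z$data else as.matrix(z)
  v <- drop(Z %*% as.numeric(r)) / ncol(Z)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-6) stop("reference uncorrelated with the observed signals")
  v / nv
}

#' Threshold-widening extraction
#'
#' When only "the component closest to the reference" is wanted and no
#' usable threshold is known, start from a tight threshold (small feasible
#' region, possibly empty) and widen it stepwise. The stabilized extractor
#' simply fails to converge while the region contains no component; the
#' first threshold at which it converges yields the desired component.
#'
#' @param z whitened signals.
#' @param r normalized reference.
#' @param cfg \code{\link{icar_config}}; its \code{xi} is overridden by the
#'   schedule.
#' @param xi_start tightest threshold (for \code{corr}: most negative).
#' @param xi_step increment applied per round (positive; widening).
#' @param xi_stop loosest threshold to try.
#' @param spec \code{\link{contrast_spec}}.
#' @return The first converged \code{"icar_extraction"} with an added
#'   \code{xi_used} element, or the last nonconvergent result (with
#'   \code{xi_used = NA}) if the whole schedule fails.
#' @export
adaptive_threshold_extract <- function(z, r, cfg = icar_config(init = "center"),
                                       xi_start, xi_step, xi_stop,
                                       spec = contrast_spec()) {
  if (cfg$measure == "corr") {
    if (!(xi_start < xi_stop && xi_stop <= 0)) stop("need xi_start < xi_stop <= 0")
  } else {
    if (!(xi_start > xi_stop)) stop("for mse, widening means decreasing xi")
  }
  if (xi_step <= 0) stop("xi_step must be positive")
  dir <- if (cfg$measure == "corr") 1 else -1
  xis <- seq(xi_start, xi_stop, by = dir * xi_step)
  if (utils::tail(xis, 1) != xi_stop) xis <- c(xis, xi_stop)
  res <- NULL
  for (xi in xis) {
    cfg$xi <- xi
    res <- extract_one(z, r, cfg, spec)
    if (res$status != "nonconvergent") { res$xi_used <- xi; return(res) }
  }
  res$xi_used <- NA_real_
  res
}

#' Recover all independent components one by one
#'
#' Repeatedly runs the stabilized one-unit extractor with a loose
#' closeness threshold, decorrelates each accepted component against the
#' previous ones, deflates the reference, and stops when an attempt fails
#' to converge -- the signal that no extractable (non-Gaussian) component
#' correlated with the remaining reference is left. Unlike deflationary
#' FastICA, the outputs are not forcibly orthogonalized against each
#' other (only the bookkeeping copies used for deflation are), estimation
#' errors do not accumulate, and Gaussian sensor noise directions are
#' never reported as components.
#'
#' @param x observed signals (\code{\link{signal_matrix}} or matrix,
#'   channels x samples), not yet whitened.
#' @param cfg \code{\link{icar_config}}; a loose threshold such as the
#'   default xi = -0.05 is appropriate here.
#' @param spec \code{\link{contrast_spec}}.
#' @param initial_reference \code{"sum_of_channels"} (default), a channel
#'   index, or a numeric trace.
#' @param max_components cap on the number of components (default: the
#'   retained whitening rank).
#' @param noise_cutoff flag recovered components whose |excess kurtosis|
#'   falls below this value as likely noise.
#' @return Object of class \code{"icar_recovery"}: \code{sources} (matrix,
#'   one row per recovered component, unit variance), \code{results}
#'   (list of \code{icar_extraction}), \code{references_used},
#'   \code{stop_reason} (\code{"nonconvergence_reached"} or
#'   \code{"max_components"}), \code{per_ic_kurtosis}, \code{noise_flags},
#'   and the \code{whitening} model.
#' @export
recover_all <- function(x, cfg = icar_config(xi = -0.05, init = "center"),
                        spec = contrast_spec(),
                        initial_reference = "sum_of_channels",
                        max_components = NULL, noise_cutoff = 0.7) {
  x <- .as_signal(x)
  wh <- whiten_signals(center_signals(x), rank_tol = cfg$rank_tol)
  Z <- wh$signals$data
  k <- nrow(Z)
  if (is.null(max_components)) max_components <- k
  max_components <- min(max_components, k)

  r <- if (identical(initial_reference, "sum_of_channels")) {
    reference_signal(colSums(x$data))
  } else if (is.numeric(initial_reference) && length(initial_reference) == 1L) {
    channel_reference(x, initial_reference)
  } else {
    reference_signal(initial_reference)
  }

  results <- list(); refs <- list(r)
  sources <- NULL
  stop_reason <- "max_components"
  while (length(results) < max_components) {
    res <- extract_one(Z, r, cfg, spec)
    if (res$status == "nonconvergent") { stop_reason <- "nonconvergence_reached"; break }
    y <- reorthogonalize_ic(res$source / sqrt(mean(res$source^2)),
                            if (is.null(sources)) list() else sources)
    sources <- rbind(sources, y)
    results <- c(results, list(res))
    r_ok <- tryCatch(deflate_reference(r, y), error = function(e) NULL)
    if (is.null(r_ok)) { stop_reason <- "nonconvergence_reached"; break }
    r <- r_ok
    refs <- c(refs, list(r))
  }
  kur <- if (is.null(sources)) numeric(0) else apply(sources, 1, excess_kurtosis)
  structure(list(sources = sources, results = results,
                 references_used = refs, stop_reason = stop_reason,
                 per_ic_kurtosis = kur,
                 noise_flags = abs(kur) < noise_cutoff,
                 whitening = wh$model),
            class = "icar_recovery")
}

#' @export
print.icar_recovery <- function(x, ...) {
  n <- length(x$results)
  cat(sprintf("icar_recovery: %d component%s (stop: %s)\n",
              n, if (n == 1) "" else "s", x$stop_reason))
  if (n > 0) {
    cat("  kurtosis:", paste(sprintf("%.3f", x$per_ic_kurtosis), collapse = ", "), "\n")
    if (any(x$noise_flags)) cat("  flagged as noise:", which(x$noise_flags), "\n")
  }
  invisible(x)
}
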