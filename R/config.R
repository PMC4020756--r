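#' Configuration for the one-unit ICA-R extractor
#'
#' @param xi closeness threshold of the inequality constraint
#'   epsilon(y, r) <= xi. For \code{measure = "corr"} it must lie in
#'   (-1, 0) (e.g. -0.5: the output must correlate at least 0.5 with the
#'   reference); for \code{"mse"} in (0, 4).
#' @param measure closeness measure, \code{"corr"} (default) or \code{"mse"}.
#' @param eta learning rate of the Newton-like weight update, in (0, 1].
#' @param gamma learning rate of the inequality multiplier update.
#' @param max_iter iteration budget per attempt (an attempt ends at
#'   convergence, at a detected failure, or here).
#' @param tol convergence tolerance: the update stops when
#'   <w_t, w_{t-1}> > 1 - tol (sign-sensitive; the reference pins the sign).
#' @param max_restarts restart budget after the initial attempt.
#' @param seed optional integer; when given, the extractor seeds the RNG.
#' @param mu_jitter_tol jitter tolerance of the secondary-increment
#'   detector and of the "multiplier has decayed" convergence guard.
#' @param lr_halving halve the learning rate once when an attempt reaches
#'   half its iteration budget without converging (helps capture weak,
#'   low-negentropy components).
#' @param init \code{"random"} (uniform on the sphere; the benchmark
#'   protocol) or \code{"center"} (start at the constraint center
#'   normalize(E{z r}), recommended for application workflows).
#' @param gauss_sig_z z-multiple for the negentropy significance test
#'   |E{G(y)} - E{G(nu)}| > z * SE; below it the candidate output is
#'   treated as Gaussian noise and never accepted as a component.
#' @param delta_persist number of consecutive significant negative-curvature
#'   iterations that triggers a restart.
#' @param stabilized use |delta| in the weight update (descent even where
#'   the curvature is negative). The legacy variants set this to FALSE.
#' @param theta_max cap on the angular step (radians) along the great
#'   circle of the unit sphere.
#' @param rank_tol relative eigenvalue cutoff used when whitening.
#' @return An object of class \code{"icar_config"}.
#' @export
icar_config <- function(xi = -0.5, measure = c("corr", "mse"), eta = 0.1,
                        gamma = 1, max_iter = 1000, tol = 1e-6,
                        max_restarts = 10, seed = NULL,
                        mu_jitter_tol = 1e-8, lr_halving = TRUE,
                        init = c("random", "center"),
                        gauss_sig_z = 3, delta_persist = 10,
                        stabilized = TRUE, theta_max = 0.5,
                        rank_tol = 1e-10) {
  measure <- match.arg(measure)
  init <- match.arg(init)
  if (measure == "corr" && (xi <= -1 || xi >= 0))
    stop("for measure = 'corr', xi must be in (-1, 0)")
  if (measure == "mse" && (xi <= 0 || xi >= 4))
    stop("for measure = 'mse', xi must be in (0, 4)")
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]")
  if (gamma <= 0) stop("gamma must be positive")
  if (max_iter < 1 || max_restarts < 0) stop("invalid iteration limits")
  if (tol <= 0 || mu_jitter_tol <= 0) stop("tolerances must be positive")
  structure(list(xi = xi, measure = measure, eta = eta, gamma = gamma,
                 max_iter = as.integer(max_iter), tol = tol,
                 max_restarts = as.integer(max_restarts), seed = seed,
                 mu_jitter_tol = mu_jitter_tol, lr_halving = lr_halving,
                 init = init, gauss_sig_z = gauss_sig_z,
                 delta_persist = as.integer(delta_persist),
                 stabilized = stabilized, theta_max = theta_max,
                 rank_tol = rank_tol),
            class = "icar_config")
}

#' @export
print.icar_config <- function(x, ...) {
  cat(sprintf("icar_config: xi = %g (%s), eta = %g, gamma = %g, max_iter = %d, max_restarts = %d\n",
              x$xi, x$measure, x$eta, x$gamma, x$max_iter, x$max_restarts))
  invisible(x)
}
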