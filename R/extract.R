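#' Projected update of the inequality multiplier
#'
#' One augmented-Lagrangian ascent step with projection onto the
#' nonnegative orthant: max(0, mu + gamma * g), where g = epsilon(y, r) - xi
#' is the constraint violation.
#'
#' @param mu current multiplier (nonnegative).
#' @param g_value constraint value epsilon(y, r) - xi.
#' @param gamma multiplier learning rate.
#' @return Updated nonnegative multiplier.
#' @export
update_multiplier <- function(mu, g_value, gamma) {
  stopifnot(mu >= 0, gamma > 0)
  max(0, mu + gamma * g_value)
}

# Incremental 4-state machine over the multiplier trace:
# pre_rise -> rising -> declining -> re_rising. A secondary increment
# (re-rise after a completed rise-and-decline, beyond the jitter
# tolerance) is the early-warning signal of misconvergence.
.mu_machine_new <- function() list(phase = "pre_rise", peak = 0, trough = 0)
.mu_machine_step <- function(st, mu, jit) {
  if (st$phase == "pre_rise") {
    if (mu > jit) { st$phase <- "rising"; st$peak <- mu }
  } else if (st$phase == "rising") {
    if (mu > st$peak) st$peak <- mu
    else if (st$peak - mu > jit) { st$phase <- "declining"; st$trough <- mu }
  } else if (st$phase == "declining") {
    if (mu < st$trough) st$trough <- mu
    else if (mu - st$trough > jit) st$phase <- "re_rising"
  }
  st
}

#' Detect a secondary increment of the inequality multiplier
#'
#' Scans a multiplier trace for the pattern rise, decline, re-rise (each
#' leg exceeding the jitter tolerance). A successful extraction shows at
#' most one fluctuation of mu; a second rise means the iterate left the
#' feasible region again, i.e. the learning is oscillating at the
#' constraint border.
#'
#' @param trace numeric vector of multiplier values (all >= 0).
#' @param jitter_tol fluctuations at or below this size are ignored.
#' @return TRUE if a secondary increment occurred.
#' @examples
#' detect_secondary_increment(c(0, 1, 2, 1, 0.2, 0, 0))   # FALSE
#' detect_secondary_increment(c(0, 1, 2, 1, 0.2, 0.8))    # TRUE
#' @export
detect_secondary_increment <- function(trace, jitter_tol = 1e-8) {
  st <- .mu_machine_new()
  for (mu in trace) {
    st <- .mu_machine_step(st, mu, jitter_tol)
    if (st$phase == "re_rising") return(TRUE)
  }
  FALSE
}

#' Orthogonal restart vector
#'
#' Draws a random unit vector and Gram-Schmidt-orthogonalizes it against
#' all previously used initial vectors, so each restart explores a
#' direction at a right angle to everything already tried.
#'
#' @param used_inits list of mutually orthonormal unit vectors (possibly
#'   empty).
#' @param dim dimension of the whitened space.
#' @return Unit vector orthogonal (|dot| < 1e-10) to every element of
#'   \code{used_inits}.
#' @export
restart_vector <- function(used_inits, dim) {
  if (length(used_inits) >= dim) stop("initial pool exhausted")
  repeat {
    v <- stats::rnorm(dim)
    for (u in used_inits) v <- v - sum(v * u) * u
    # re-orthogonalize once for numerical hygiene
    for (u in used_inits) v <- v - sum(v * u) * u
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# closeness pieces for the learning rule, on whitened data.
# y: current output; v: samples of the step direction u (v = u'z);
# Zr: E{z r}; eps: current closeness; all per-measure.
.eps_grad_w <- function(measure, w, Zr, Zy) {
  if (measure == "corr") -Zr else 2 * (Zy - Zr)
}

#' One Newton-like update of the demixing vector
#'
#' Performs a damped Newton step along the great circle of the unit
#' sphere (so the weight stays normalized by construction). With
#' y = w'z, the augmented Lagrangian being minimized is
#' f(w) = -rho (E{G(y)} - E{G(nu)})^2
#'        + (1/(2 gamma)) (max(0, mu + gamma (eps(y,r) - xi))^2 - mu^2).
#' The gradient is exact; the Newton denominator delta is the directional
#' curvature of f with the negentropy slope rho_bar = 2 rho (E{G} - E{G(nu)})
#' frozen at the current iterate (the classical Newton-like approximation
#' of one-unit ICA learning). delta is positive near every true component,
#' of either kurtosis sign, and negative in wrong-basin or transition
#' regions; the caller inspects its sign.
#'
#' @param w unit-norm weight vector (length k).
#' @param z whitened signal matrix (k x n), a \code{\link{signal_matrix}}
#'   or plain matrix.
#' @param r normalized \code{\link{reference_signal}}.
#' @param mu current (pre-update) inequality multiplier.
#' @param spec \code{\link{contrast_spec}}.
#' @param cfg \code{\link{icar_config}}.
#' @param C optional covariance matrix for unwhitened operation: the step
#'   is then taken in the flat coordinates and the result rescaled so that
#'   the output variance w'Cw equals 1 (replacing the normalization).
#' @return List with \code{w_new}, \code{delta} (signed curvature),
#'   \code{grad} (flat gradient of f), \code{mu_new} (projected updated
#'   multiplier), \code{eps}, \code{rho_bar}, \code{theta} (angular step
#'   taken) and \code{significant} (negentropy significance flag).
#' @export
newton_step <- function(w, z, r, mu, spec = contrast_spec(), cfg = icar_config(),
                        C = NULL) {
  Z <- if (inherits(z, "signal_matrix")) z$data else z
  n <- ncol(Z)
  r <- as.numeric(r)
  Zr <- drop(Z %*% r) / n
  st <- .newton_core(w, Z, r, mu, spec, cfg, Zr, eta_cur = cfg$eta, C = C)
  if (abs(st$delta) < 1e-12) stop("singular Newton denominator")
  st
}

# Core of one iteration; shared by newton_step, extract_one and the
# lin_fast legacy variant. Returns the updated weight and diagnostics.
.newton_core <- function(w, Z, r, mu, spec, cfg, Zr, eta_cur, C = NULL) {
  n <- ncol(Z)
  y <- drop(crossprod(w, Z))
  if (!is.null(C)) {                     # unwhitened mode: normalize output scale
    sy <- sqrt(drop(crossprod(w, C %*% w)))
    y <- y / sy
  }
  eps <- if (cfg$measure == "corr") -mean(y * r) else mean((y - r)^2)
  g <- eps - cfg$xi
  mu_new <- update_multiplier(mu, g, cfg$gamma)
  Gy <- spec$G(y); gy <- spec$g(y); gpy <- spec$gprime(y)
  mG <- mean(Gy)
  rho_bar <- 2 * spec$rho * (mG - spec$gauss_moment)
  significant <- abs(mG - spec$gauss_moment) >
    cfg$gauss_sig_z * stats::sd(Gy) / sqrt(n)
  Zy <- w  # E{z y} = w for whitened unit-covariance z
  grad <- -(rho_bar / n) * drop(Z %*% gy)
  active <- mu_new > 0
  if (active) grad <- grad + mu_new * .eps_grad_w(cfg$measure, w, Zr, Zy)

  if (!is.null(C)) {
    # flat step (legacy unwhitened flavor), then variance normalization
    delta <- -rho_bar * mean(gpy) + if (active) mu_new * (if (cfg$measure == "corr") 0 else 2) else 0
    dd <- if (cfg$stabilized) abs(delta) else delta
    if (abs(dd) < 1e-12) stop("singular Newton denominator")
    w2 <- w - eta_cur * grad / dd
    w2 <- w2 / sqrt(drop(crossprod(w2, C %*% w2)))
    return(list(w_new = w2, delta = delta, grad = grad, mu_new = mu_new,
                eps = eps, rho_bar = rho_bar, theta = NA_real_,
                significant = significant, converged_step = FALSE))
  }

  gt <- grad - sum(grad * w) * w
  ng <- sqrt(sum(gt^2))
  if (ng < 1e-14) {
    return(list(w_new = w, delta = NA_real_, grad = grad, mu_new = mu_new,
                eps = eps, rho_bar = rho_bar, theta = 0,
                significant = significant, converged_step = TRUE))
  }
  u <- gt / ng
  v <- drop(crossprod(u, Z))
  # curvature of the frozen-slope model along the great circle through u
  delta <- -rho_bar * (mean(gpy * v * v) - mean(y * gy))
  if (active) {
    if (cfg$measure == "corr") {
      epsd1 <- -mean(r * v)          # d eps / d theta
      epsd2 <- -eps                  # d^2 eps / d theta^2 at theta = 0
    } else {
      epsd1 <- 2 * mean((y - r) * v)
      epsd2 <- 2 * (mean(v^2) - mean(y^2) + mean(y * r))
    }
    delta <- delta + mu_new * epsd2 + cfg$gamma * epsd1^2
  }
  dd <- if (cfg$stabilized) abs(delta) else delta
  if (abs(dd) < 1e-12) dd <- sign(dd + (dd == 0)) * 1e-12
  theta <- -eta_cur * ng / dd
  if (abs(theta) > cfg$theta_max) theta <- sign(theta) * cfg$theta_max
  w2 <- w * cos(theta) + u * sin(theta)
  list(w_new = w2, delta = delta, grad = grad, mu_new = mu_new,
       eps = eps, rho_bar = rho_bar, theta = theta,
       significant = significant, converged_step = FALSE)
}

# tangential Hessian positive-definiteness check at a candidate optimum
.tangent_hessian_pd <- function(w, Z, y, gpy, gy, rho_bar) {
  k <- length(w); n <- ncol(Z)
  M <- -rho_bar * ((Z * rep(gpy, each = k)) %*% t(Z) / n - mean(y * gy) * diag(k))
  P <- diag(k) - tcrossprod(w)
  ev <- eigen(P %*% M %*% P, symmetric = TRUE, only.values = TRUE)$values
  all(ev[seq_len(k - 1)] > 0)
}

#' Extract one independent component guided by a reference
#'
#' The stabilized fast one-unit ICA-R extractor. Starting from a random
#' (or constraint-center) unit vector, it iterates multiplier update,
#' Newton-like weight update along the unit sphere, and convergence check;
#' it monitors the inequality multiplier for a secondary increment and the
#' Newton curvature for persistent negativity, and restarts from a
#' Gram-Schmidt-orthogonal initial vector when either failure signal
#' fires. Convergence is only accepted at a feasible point where the
#' multiplier has decayed to zero, the negentropy of the output is
#' statistically significant, and the projected Hessian is positive
#' definite -- so a converged result is a true component satisfying the
#' closeness constraint, never a border-trapped fake.
#'
#' @param z whitened signals (\code{\link{signal_matrix}} or k x n matrix).
#' @param r normalized \code{\link{reference_signal}}.
#' @param cfg \code{\link{icar_config}}.
#' @param spec \code{\link{contrast_spec}}.
#' @param detect enable the failure detectors and restarts (Step 8). With
#'   \code{detect = FALSE} the loop is the plain fast one-unit iteration.
#' @param keep_traces record per-iteration mu, delta, closeness and step
#'   angle (on by default; turn off in tight benchmark loops).
#' @return Object of class \code{"icar_extraction"}: \code{weight} (unit
#'   vector), \code{source} (the extracted output w'z), \code{status}
#'   (\code{"converged"}, \code{"converged_after_restart"} or
#'   \code{"nonconvergent"}), \code{iterations} (total), \code{restarts},
#'   \code{mu_trace}, \code{delta_trace}, \code{used_inits},
#'   \code{closeness_final}, \code{xi} and \code{eta_final}.
#' @export
extract_one <- function(z, r, cfg = icar_config(), spec = contrast_spec(),
                        detect = TRUE, keep_traces = TRUE) {
  Z <- if (inherits(z, "signal_matrix")) z$data else as.matrix(z)
  r <- as.numeric(r)
  if (length(r) != ncol(Z)) stop("reference length does not match sample count")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  k <- nrow(Z); n <- ncol(Z)
  Zr <- drop(Z %*% r) / n

  new_init <- function(pool) {
    if (cfg$init == "center" && length(pool) == 0L) {
      nc <- sqrt(sum(Zr^2))
      if (nc > 1e-8) return(Zr / nc)
    }
    if (length(pool) >= k) pool <- list()   # pool reset
    restart_vector(pool, k)
  }

  used <- list()
  w <- new_init(used)
  w0 <- w
  restarts <- 0L; total_it <- 0L
  mu_all <- numeric(0); delta_all <- numeric(0)
  eps_all <- numeric(0); theta_all <- numeric(0)
  eta_res <- cfg$eta

  repeat {
    if (sum(w * Zr) < 0) { w <- -w; w0 <- -w0 }   # reference pins the sign
    mu <- 0
    mstate <- .mu_machine_new()
    eta_cur <- eta_res
    halved <- FALSE
    ok <- FALSE; fail <- FALSE
    dneg_run <- 0L
    mu_tr <- numeric(cfg$max_iter); delta_tr <- numeric(cfg$max_iter)
    eps_tr <- numeric(cfg$max_iter); theta_tr <- numeric(cfg$max_iter)
    it <- 0L
    last <- NULL

    while (it < cfg$max_iter) {
      it <- it + 1L
      st <- .newton_core(w, Z, r, mu, spec, cfg, Zr, eta_cur)
      mu <- st$mu_new
      mu_tr[it] <- mu
      delta_tr[it] <- if (is.na(st$delta)) 0 else st$delta
      eps_tr[it] <- st$eps
      theta_tr[it] <- if (is.na(st$theta)) 0 else st$theta
      last <- st

      if (detect) {
        mstate <- .mu_machine_step(mstate, mu, cfg$mu_jitter_tol)
        if (mstate$phase == "re_rising") { fail <- TRUE; break }
        if (!is.na(st$delta) && st$delta < 0 && st$significant)
          dneg_run <- dneg_run + 1L else dneg_run <- 0L
        if (dneg_run >= cfg$delta_persist) { fail <- TRUE; break }
      }

      conv <- st$converged_step || sum(st$w_new * w) > 1 - cfg$tol
      w <- st$w_new

      if (conv && st$eps <= cfg$xi + 1e-6) {
        if (!detect) { ok <- TRUE; break }
        if (!st$significant) { fail <- TRUE; break }        # Gaussian-level output
        if (mu > cfg$mu_jitter_tol) { fail <- TRUE; break } # constraint still active
        y <- drop(crossprod(w, Z))
        if (.tangent_hessian_pd(w, Z, y, spec$gprime(y), spec$g(y),
                                2 * spec$rho * (mean(spec$G(y)) - spec$gauss_moment))) {
          ok <- TRUE
        } else fail <- TRUE
        break
      }
      if (cfg$lr_halving && !halved && it > cfg$max_iter / 2) {
        eta_cur <- eta_cur / 2; halved <- TRUE
      }
    }

    total_it <- total_it + it
    if (keep_traces && it > 0L) {
      mu_all <- c(mu_all, mu_tr[seq_len(it)])
      delta_all <- c(delta_all, delta_tr[seq_len(it)])
      eps_all <- c(eps_all, eps_tr[seq_len(it)])
      theta_all <- c(theta_all, theta_tr[seq_len(it)])
    }

    if (ok || !detect) {
      status <- if (ok && restarts == 0L) "converged"
        else if (ok) "converged_after_restart"
        else "nonconvergent"
      return(.finish_extraction(w, Z, r, cfg, status, total_it, restarts,
                                mu_all, delta_all, eps_all, theta_all,
                                used, eta_cur))
    }

    restarts <- restarts + 1L
    if (restarts > cfg$max_restarts) {
      return(.finish_extraction(w, Z, r, cfg, "nonconvergent", total_it,
                                restarts - 1L, mu_all, delta_all, eps_all,
                                theta_all, used, eta_cur))
    }
    if (restarts %% 3L == 0L) eta_res <- max(cfg$eta / 16, eta_res / 2)
    used <- c(used, list(w0))
    if (length(used) >= k) used <- list()
    w <- restart_vector(used, k)
    w0 <- w
  }
}

.finish_extraction <- function(w, Z, r, cfg, status, iterations, restarts,
                               mu_trace, delta_trace, eps_trace, theta_trace,
                               used_inits, eta_final) {
  y <- drop(crossprod(w, Z))
  eps <- if (cfg$measure == "corr") -mean(y * r) else mean((y - r)^2)
  structure(list(weight = w, source = y, status = status,
                 iterations = iterations, restarts = restarts,
                 mu_trace = mu_trace, delta_trace = delta_trace,
                 closeness_trace = eps_trace, theta_trace = theta_trace,
                 used_inits = used_inits, closeness_final = eps,
                 xi = cfg$xi, measure = cfg$measure, eta_final = eta_final),
            class = "icar_extraction")
}

#' @export
print.icar_extraction <- function(x, ...) {
  cat(sprintf("icar_extraction: %s after %d iterations (%d restart%s), closeness %.4f (xi = %g)\n",
              x$status, x$iterations, x$restarts,
              if (x$restarts == 1) "" else "s", x$closeness_final, x$xi))
  invisible(x)
}

#' Legacy one-unit ICA-R extractors
#'
#' The two earlier learning rules, kept as baselines for the
#' misconvergence benchmark. Neither detects failures nor restarts; each
#' run reports wherever it lands, including wrong (border-trapped) points.
#'
#' \describe{
#'   \item{\code{lin_fast}}{the fast variant: pre-whitened data,
#'     per-iteration weight normalization, no equality constraint, raw
#'     (unstabilized) Newton denominator. Runs that oscillate until the
#'     iteration budget are reported \code{"nonconvergent"}.}
#'   \item{\code{lu_original}}{the original flat-space rule: no
#'     normalization; the unit-variance equality constraint h(w) =
#'     E{y^2} - 1 is kept with a multiplier lambda updated by gradient
#'     ascent. The weight can genuinely diverge (reported
#'     \code{"diverged"}) when the Hessian term goes negative.}
#' }
#'
#' @param z whitened signals.
#' @param r normalized reference.
#' @param cfg \code{\link{icar_config}} (its \code{stabilized} flag is
#'   ignored; legacy steps are raw).
#' @param spec \code{\link{contrast_spec}}.
#' @param variant \code{"lin_fast"} or \code{"lu_original"}.
#' @return An \code{"icar_extraction"} object (status may additionally be
#'   \code{"diverged"} for \code{lu_original}).
#' @export
extract_one_legacy <- function(z, r, cfg = icar_config(), spec = contrast_spec(),
                               variant = c("lin_fast", "lu_original")) {
  variant <- match.arg(variant)
  if (variant == "lin_fast") {
    cfg$stabilized <- FALSE
    cfg$init <- "random"
    cfg$lr_halving <- FALSE   # the legacy rule ran at a fixed learning rate
    return(extract_one(z, r, cfg, spec, detect = FALSE))
  }
  .extract_lu(z, r, cfg, spec)
}

# Lu-style flat iteration with equality multiplier, no normalization.
.extract_lu <- function(z, r, cfg, spec) {
  Z <- if (inherits(z, "signal_matrix")) z$data else as.matrix(z)
  r <- as.numeric(r)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  k <- nrow(Z); n <- ncol(Z)
  Zr <- drop(Z %*% r) / n
  w <- stats::rnorm(k); w <- w / sqrt(sum(w^2))
  if (sum(w * Zr) < 0) w <- -w
  mu <- 0; lambda <- 0
  mu_tr <- numeric(cfg$max_iter); delta_tr <- numeric(cfg$max_iter)
  eps_tr <- numeric(cfg$max_iter)
  status <- "nonconvergent"; it <- 0L
  while (it < cfg$max_iter) {
    it <- it + 1L
    y <- drop(crossprod(w, Z))
    h <- mean(y^2) - 1
    yn_sd <- sqrt(mean(y^2))
    yn <- y / max(yn_sd, 1e-12)
    eps <- if (cfg$measure == "corr") -mean(yn * r) else mean((yn - r)^2)
    g <- eps - cfg$xi
    mu <- update_multiplier(mu, g, cfg$gamma)
    Gy <- spec$G(y); gy <- spec$g(y); gpy <- spec$gprime(y)
    rho_bar <- 2 * spec$rho * (mean(Gy) - spec$gauss_moment)
    grad <- -(rho_bar / n) * drop(Z %*% gy)
    if (mu > 0) grad <- grad + mu * .eps_grad_w(cfg$measure, w, Zr, drop(Z %*% y) / n)
    grad <- grad + 2 * (lambda + cfg$gamma * h) * drop(Z %*% y) / n
    delta <- -rho_bar * mean(gpy) +
      (if (mu > 0 && cfg$measure == "mse") 2 * mu else 0) +
      2 * (lambda + cfg$gamma * h)
    mu_tr[it] <- mu; delta_tr[it] <- delta; eps_tr[it] <- eps
    if (abs(delta) < 1e-12) delta <- 1e-12
    w2 <- w - cfg$eta * grad / delta
    lambda <- lambda + cfg$gamma * h
    nw <- sqrt(sum(w2^2))
    if (!is.finite(nw) || nw > 1e6) { w <- w2; status <- "diverged"; break }
    if (sum(w2 * w) / (nw * sqrt(sum(w^2))) > 1 - cfg$tol &&
        abs(h) < 1e-3 && eps <= cfg$xi + 1e-6) {
      w <- w2; status <- "converged"; break
    }
    w <- w2
  }
  nw <- sqrt(sum(w^2))
  wn <- if (is.finite(nw) && nw > 0) w / nw else w
  out <- .finish_extraction(wn, Z, r, cfg, status, it, 0L,
                            mu_tr[seq_len(it)], delta_tr[seq_len(it)],
                            eps_tr[seq_len(it)], numeric(it), list(), cfg$eta)
  out
}
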