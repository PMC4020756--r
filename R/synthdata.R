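#' Source specification for the fixture generators
#'
#' @param kind one of \code{"uniform"}, \code{"sinusoid"},
#'   \code{"sawtooth"}, \code{"laplace"}, \code{"spikes"},
#'   \code{"gaussian"}. Uniform, sinusoid and sawtooth are sub-Gaussian
#'   (excess kurtosis -1.2, -1.5, -1.2); laplace and spikes are
#'   super-Gaussian (+3 and larger); gaussian is the zero-kurtosis control.
#' @param n_samples number of time samples (>= 100).
#' @param seed integer seed for this source's draw.
#' @param freq cycles per sample for the periodic kinds (drawn at random
#'   when NULL).
#' @param spike_prob spike probability per sample for \code{"spikes"}.
#' @return Object of class \code{"source_spec"}.
#' @export
source_spec <- function(kind = c("uniform", "sinusoid", "sawtooth",
                                 "laplace", "spikes", "gaussian"),
                        n_samples = 5000, seed = 1, freq = NULL,
                        spike_prob = 0.05) {
  kind <- match.arg(kind)
  if (n_samples < 100) stop("n_samples must be at least 100")
  structure(list(kind = kind, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), freq = freq,
                 spike_prob = spike_prob,
                 target_kurtosis_sign = switch(kind,
                   uniform = , sinusoid = , sawtooth = "sub",
                   laplace = , spikes = "super", gaussian = "zero")),
            class = "source_spec")
}

.norm01 <- function(s) { s <- s - mean(s); s / sqrt(mean(s^2)) }

.gen_one_source <- function(sp) {
  set.seed(sp$seed)
  T <- sp$n_samples
  s <- switch(sp$kind,
    uniform  = stats::runif(T, -1, 1),
    sinusoid = {
      f <- if (is.null(sp$freq)) stats::runif(1, 0.005, 0.05) else sp$freq
      sin(2 * pi * f * seq_len(T) + stats::runif(1, 0, 2 * pi))
    },
    sawtooth = {
      f <- if (is.null(sp$freq)) stats::runif(1, 0.005, 0.05) else sp$freq
      ph <- stats::runif(1)
      2 * ((f * seq_len(T) + ph) %% 1) - 1
    },
    laplace  = {
      u <- stats::runif(T) - 0.5
      -sign(u) * log(1 - 2 * abs(u))
    },
    spikes   = {
      b <- stats::rbinom(T, 1, sp$spike_prob)
      b * stats::rnorm(T)
    },
    gaussian = stats::rnorm(T))
  .norm01(s)
}

#' Generate a matrix of independent normalized sources
#'
#' Each row is drawn independently according to its
#' \code{\link{source_spec}} (its own seed makes regeneration
#' bit-identical), then normalized to zero mean and unit variance.
#'
#' @param specs list of \code{source_spec} objects (same n_samples).
#' @return l x n_samples matrix of sources.
#' @export
gen_sources <- function(specs) {
  if (inherits(specs, "source_spec")) specs <- list(specs)
  ns <- vapply(specs, function(s) s$n_samples, integer(1))
  if (length(unique(ns)) != 1L) stop("all sources must share n_samples")
  t(vapply(specs, .gen_one_source, numeric(ns[1])))
}

#' Generate a mixing matrix
#'
#' With \code{dominance = TRUE}, each of the first l rows is normalized to
#' unit length with its diagonal entry bigger than 0.5 in absolute value
#' and every off-diagonal entry at most 0.5 in absolute value, so each
#' channel has a unique dominant source. Rows beyond the square part (for
#' n > l) are random unit-norm. Rank-deficient draws are resampled.
#'
#' @param n number of channels (rows), n >= l.
#' @param l number of sources (columns).
#' @param dominance enforce the diagonal-dominance rule.
#' @param seed integer seed.
#' @param off_scale scale factor applied to the off-diagonal entries
#'   before normalization (0 gives the identity when \code{dominance}).
#' @return n x l mixing matrix of full column rank.
#' @export
gen_mixing <- function(n, l, dominance = TRUE, seed = 1, off_scale = 1) {
  if (n < l) stop("need at least as many channels as sources")
  set.seed(seed)
  for (try in 1:200) {
    A <- matrix(stats::rnorm(n * l), n, l)
    if (dominance) {
      for (i in seq_len(min(n, l))) {
        off <- A[i, -i] * off_scale
        no <- sqrt(sum(off^2))
        if (no > 0) {
          u <- off / no
          # |diag| must exceed 0.5 and leave every off-diagonal entry
          # at most 0.5 after the row is scaled to unit length
          dmin <- max(0.55, sqrt(max(0, 1 - 0.25 / max(u^2))) + 0.01)
          d <- stats::runif(1, dmin, min(0.95, dmin + 0.35)) *
            sign(A[i, i] + (A[i, i] == 0))
          A[i, -i] <- u * sqrt(1 - d^2)
          A[i, i] <- d
        } else {
          A[i, -i] <- 0
          A[i, i] <- sign(A[i, i] + (A[i, i] == 0))
        }
        A[i, ] <- A[i, ] / sqrt(sum(A[i, ]^2))
      }
      if (n > l) for (i in (l + 1):n) A[i, ] <- A[i, ] / sqrt(sum(A[i, ]^2))
    }
    if (qr(A)$rank == l) return(A)
  }
  stop("could not draw a full-rank mixing matrix")
}

#' Build a reference with controlled correlation to a target source
#'
#' Blends the target, optional contaminant sources and independent noise
#' so that the realized correlation with the target is \code{quality} and
#' with each contaminant the requested value; the noise is
#' orthogonalized against target and contaminants so the realized
#' correlations are accurate.
#'
#' @param target source row (zero mean, unit variance).
#' @param quality requested |correlation| with the target, in (0, 1].
#' @param contaminants optional matrix/list of other source rows.
#' @param contaminant_corr correlations requested for the contaminants.
#' @param seed integer seed for the noise draw.
#' @return A \code{\link{reference_signal}}.
#' @export
make_reference <- function(target, quality, contaminants = NULL,
                           contaminant_corr = NULL, seed = 1) {
  if (quality <= 0 || quality > 1) stop("quality must be in (0, 1]")
  target <- .norm01(as.numeric(target))
  cc <- if (is.null(contaminants)) numeric(0) else as.numeric(contaminant_corr)
  if (sum(quality^2, cc^2) > 1)
    stop("infeasible correlation request: sum of squared correlations exceeds 1")
  r <- quality * target
  if (!is.null(contaminants)) {
    if (is.matrix(contaminants)) contaminants <- split(contaminants, row(contaminants))
    if (length(cc) != length(contaminants)) stop("one correlation per contaminant")
    for (i in seq_along(contaminants))
      r <- r + cc[i] * .norm01(as.numeric(contaminants[[i]]))
  }
  b2 <- 1 - sum(quality^2, cc^2)
  if (b2 > 1e-12) {
    set.seed(seed)
    nz <- stats::rnorm(length(target))
    nz <- nz - mean(nz * target) * target
    if (!is.null(contaminants)) for (cs in contaminants) {
      cs <- .norm01(as.numeric(cs)); nz <- nz - mean(nz * cs) * cs
    }
    r <- r + sqrt(b2) * .norm01(nz)
  }
  reference_signal(r)
}

#' Mixture fixture container
#'
#' @param sources l x T source matrix.
#' @param mixing n x l mixing matrix.
#' @param noise_sd standard deviation of added sensor noise (0 = none).
#' @param seed seed for the noise draw.
#' @return Object of class \code{"mixture_fixture"} with \code{sources},
#'   \code{mixing}, \code{observations} (= mixing \%*\% sources + noise)
#'   and \code{noise_sd}.
#' @export
mixture_fixture <- function(sources, mixing, noise_sd = 0, seed = 1) {
  X <- mixing %*% sources
  if (noise_sd > 0) {
    set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X))
  }
  structure(list(sources = sources, mixing = mixing, observations = X,
                 noise_sd = noise_sd, seed = seed),
            class = "mixture_fixture")
}

#' @export
print.mixture_fixture <- function(x, ...) {
  cat(sprintf("mixture_fixture: %d sources -> %d channels, %d samples%s\n",
              nrow(x$sources), nrow(x$observations), ncol(x$sources),
              if (x$noise_sd > 0) sprintf(", noise sd %.3g", x$noise_sd) else ""))
  invisible(x)
}

#' Transformed coordinates of a weight vector
#'
#' Maps a whitened-space weight onto the source coordinate system
#' (q_i ~ correlation of w'z with source i), the coordinates in which the
#' attraction-basin analysis is carried out.
#'
#' @param fixture a \code{\link{mixture_fixture}}.
#' @param z whitened observations of the fixture.
#' @param w unit weight vector in whitened space.
#' @return Numeric vector q of length l (unit norm up to sampling error).
#' @export
transformed_coordinates <- function(fixture, z, w) {
  Z <- if (inherits(z, "signal_matrix")) z$data else as.matrix(z)
  y <- drop(crossprod(w, Z))
  drop(fixture$sources %*% y) / ncol(Z)
}

#' The two-source misconvergence counterexample
#'
#' Two sub-Gaussian sources with excess kurtoses close to -1.291 and
#' -1.498 (a flattened uniform sign(u)|u|^0.905 and a random-phase
#' sinusoid), mixed 2 x 2 with row-normalized dominant diagonal; a
#' reference whose closenesses to the two sources are -0.8907 and
#' -0.4166; threshold xi = -0.6, so only the first source is feasible.
#' On this problem the legacy extractor has a sizable probability of
#' oscillating at the constraint border (misconvergence) while the
#' stabilized extractor recovers the feasible source.
#'
#' @param seed integer seed.
#' @param n_samples samples per source.
#' @return List with \code{fixture} (a \code{\link{mixture_fixture}}),
#'   \code{reference}, \code{config} (xi = -0.6) and \code{closeness}
#'   (realized closeness of the reference to each source).
#' @export
counterexample_fixture <- function(seed = 1, n_samples = 5000) {
  set.seed(seed)
  u <- stats::runif(n_samples, -1, 1)
  s1 <- .norm01(sign(u) * abs(u)^0.905)      # excess kurtosis -1.291
  f <- stats::runif(1, 0.005, 0.05)
  s2 <- .norm01(sin(2 * pi * f * seq_len(n_samples) + stats::runif(1, 0, 2 * pi)))
  S <- rbind(s1, s2)
  dimnames(S) <- NULL
  A <- matrix(c(0.8, 0.6, -0.55, 0.835), 2, 2, byrow = TRUE)
  A <- A / sqrt(rowSums(A^2))
  fx <- mixture_fixture(S, A)
  r <- make_reference(s1, 0.8907, contaminants = rbind(s2),
                      contaminant_corr = 0.4166, seed = seed + 1)
  list(fixture = fx, reference = r,
       config = icar_config(xi = -0.6),
       closeness = c(-mean(as.numeric(r) * s1), -mean(as.numeric(r) * s2)))
}

#' Standard four-source benchmark fixture
#'
#' Two sub-Gaussian sources (uniform noise and a random-phase sinusoid,
#' indices 1 and 3) and two super-Gaussian sources (Laplace and a spike
#' train, indices 2 and 4), mixed by a row-normalized matrix with
#' dominant diagonal. This is the fixture the misconvergence benchmark
#' protocol runs on.
#'
#' @param seed integer seed.
#' @param n_samples samples per source.
#' @return A \code{\link{mixture_fixture}}.
#' @export
four_source_fixture <- function(seed = 1, n_samples = 5000) {
  S <- gen_sources(list(source_spec("uniform", n_samples, seed),
                        source_spec("laplace", n_samples, seed + 1),
                        source_spec("sinusoid", n_samples, seed + 2),
                        source_spec("spikes", n_samples, seed + 3)))
  mixture_fixture(S, gen_mixing(4, 4, dominance = TRUE, seed = seed + 4))
}

#' ECG-like synthetic fixture
#'
#' Emulates an 8-channel maternal abdominal recording: two strong
#' maternal-like periodic spike trains (super-Gaussian), one weaker and
#' faster fetal-like spike train, and one slow breathing-like oscillation,
#' mixed into 8 channels with Gaussian sensor noise. Channel 1 is weighted
#' towards the fetal-like source, so it can serve as a direct reference
#' for fetal extraction. Source order: maternal1, maternal2, fetal,
#' breathing.
#'
#' @param seed integer seed.
#' @param n_samples samples.
#' @param fetal_amplitude mixing weight of the fetal-like source relative
#'   to the maternal ones (default 0.2).
#' @param noise_sd sensor noise standard deviation.
#' @return A \code{\link{mixture_fixture}} (with \code{fetal = 3} marking
#'   the fetal row).
#' @export
ecg_like_fixture <- function(seed = 1, n_samples = 5000,
                             fetal_amplitude = 0.2, noise_sd = 0.05) {
  set.seed(seed)
  T <- n_samples
  beat <- function(period, width, jitter = 0.1) {
    centers <- seq(stats::runif(1, 1, period), T, by = period)
    centers <- centers + stats::rnorm(length(centers), sd = jitter * period / 10)
    s <- numeric(T)
    t <- seq_len(T)
    for (cc in centers) {
      idx <- t[abs(t - cc) < 4 * width]
      s[idx] <- s[idx] + exp(-(idx - cc)^2 / (2 * width^2))
    }
    .norm01(s)
  }
  m1 <- beat(70, 2)
  m2 <- beat(70, 3); m2 <- .norm01(m2 - mean(m2 * m1) * m1)
  fe <- beat(42, 1.5)
  br <- .norm01(sin(2 * pi * seq_len(T) / stats::runif(1, 700, 900) +
                      stats::runif(1, 0, 2 * pi)))
  S <- rbind(m1, m2, fe, br)
  A <- matrix(stats::rnorm(32), 8, 4)
  A[, 3] <- A[, 3] * fetal_amplitude
  A[1, ] <- c(0.2, 0.2, 0.9 * fetal_amplitude, 0.1)  # fetal-dominated lead
  fx <- mixture_fixture(S, A, noise_sd = noise_sd, seed = seed + 1)
  fx$fetal <- 3L
  fx
}
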