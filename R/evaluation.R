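#' Signal-to-noise ratio of a recovered component, in dB
#'
#' Both vectors are centered and scaled to unit Euclidean norm, the
#' estimate's sign is aligned with the truth, and the SNR is
#' 10 log10( ||truth||^2 / ||truth - estimate||^2 ). An exact recovery is
#' reported as the cap value 300 dB.
#'
#' @param estimate recovered component.
#' @param truth true source (must have positive variance).
#' @param cap upper bound in dB for (near-)exact recoveries.
#' @return SNR in dB.
#' @export
snr_db <- function(estimate, truth, cap = 300) {
  truth <- as.numeric(truth); estimate <- as.numeric(estimate)
  if (length(truth) != length(estimate)) stop("length mismatch")
  tc <- truth - mean(truth)
  nt <- sqrt(sum(tc^2))
  if (nt == 0) stop("zero-variance truth")
  tc <- tc / nt
  ec <- estimate - mean(estimate)
  ne <- sqrt(sum(ec^2))
  if (ne == 0) return(0)
  ec <- ec / ne
  if (sum(ec * tc) < 0) ec <- -ec
  mse <- sum((tc - ec)^2)
  if (mse <= sum(tc^2) * 10^(-cap / 10)) return(cap)
  min(cap, 10 * log10(sum(tc^2) / mse))
}

#' Match recovered components to true sources
#'
#' Greedy assignment by decreasing |correlation|; each truth is used at
#' most once, surplus estimates stay unmatched.
#'
#' @param estimates matrix (rows = recovered components) or list.
#' @param truths matrix (rows = true sources) or list.
#' @return List with \code{matches} (data frame: estimate, truth,
#'   correlation -- signed) and \code{unmatched} (estimate indices).
#' @export
match_components <- function(estimates, truths) {
  E <- if (is.matrix(estimates)) estimates else do.call(rbind, estimates)
  S <- if (is.matrix(truths)) truths else do.call(rbind, truths)
  ne <- nrow(E); ns <- nrow(S)
  if (is.null(ne) || ne == 0)
    return(list(matches = data.frame(estimate = integer(0), truth = integer(0),
                                     correlation = numeric(0)),
                unmatched = integer(0)))
  cm <- stats::cor(t(E), t(S))
  if (ne == 1 || ns == 1) cm <- matrix(cm, ne, ns)
  used_e <- logical(ne); used_s <- logical(ns)
  out <- NULL
  for (step in seq_len(min(ne, ns))) {
    cand <- abs(cm)
    cand[used_e, ] <- -Inf
    cand[, used_s] <- -Inf
    ij <- arrayInd(which.max(cand), dim(cand))
    i <- ij[1]; j <- ij[2]
    out <- rbind(out, data.frame(estimate = i, truth = j,
                                 correlation = cm[i, j]))
    used_e[i] <- TRUE; used_s[j] <- TRUE
  }
  list(matches = out[order(out$estimate), , drop = FALSE],
       unmatched = which(!used_e))
}

#' Classify a single extraction run against ground truth
#'
#' A run is \code{accurate} when it terminated (converged or stopped by
#' the iteration budget) with |correlation| to the desired source at
#' least \code{match_threshold}; \code{misconverged} when it terminated
#' below the threshold (a fake component); \code{nonconvergent} when the
#' stabilized extractor exhausted its restarts without accepting any
#' output; \code{diverged} when the weight blew up (legacy original
#' rule). Independently of the label, any negative Newton-curvature event
#' in the delta trace sets the \code{negative_denominator} flag; label
#' and flag may co-occur and their intersection is tabulated separately
#' in the benchmark.
#'
#' @param result an \code{"icar_extraction"}.
#' @param fixture the \code{\link{mixture_fixture}} providing the truth.
#' @param desired index of the desired source.
#' @param match_threshold |correlation| cutoff (default 0.95).
#' @return Object of class \code{"icar_run_class"}: \code{label},
#'   \code{best_corr} (signed correlation with the desired source),
#'   \code{negative_denominator}, \code{matched_source}.
#' @export
classify_run <- function(result, fixture, desired, match_threshold = 0.95) {
  y <- result$source
  ct <- drop(stats::cor(y, t(fixture$sources)))
  cd <- ct[desired]
  label <- if (result$status == "diverged") "diverged"
    else if (result$status == "nonconvergent" && result$restarts > 0) "nonconvergent"
    else if (abs(cd) >= match_threshold) "accurate"
    else "misconverged"
  structure(list(label = label, best_corr = cd,
                 negative_denominator = any(result$delta_trace < 0),
                 matched_source = if (abs(ct[which.max(abs(ct))]) >=
                                      match_threshold) which.max(abs(ct)) else NA_integer_),
            class = "icar_run_class")
}

#' Misconvergence benchmark of extractor variants
#'
#' For each desired source and each algorithm, runs the extractor
#' \code{n_trials} times with fresh random unit initial vectors and a
#' reference of fixed quality, classifies every run against the fixture
#' ground truth, and tabulates the fault counts the way the original
#' comparison does: misconvergence, negative-curvature events, and their
#' intersection. Deterministic for a fixed \code{master_seed}.
#'
#' @param fixture \code{\link{mixture_fixture}} (noise-free or noisy).
#' @param algorithms character vector from \code{"new"},
#'   \code{"lin_fast"}, \code{"lu_original"}.
#' @param n_trials runs per (source, algorithm).
#' @param cfg \code{\link{icar_config}} (init is forced to random).
#' @param spec \code{\link{contrast_spec}}.
#' @param desired_ics source indices to benchmark (default: all).
#' @param ref_quality |correlation| of the generated reference with the
#'   desired source.
#' @param match_threshold accuracy cutoff.
#' @param master_seed master seed.
#' @return Object of class \code{"icar_benchmark"}: \code{counts} (data
#'   frame with algorithm, desired IC, n_trials, accurate, misconverged,
#'   negative_denominator, intersection, nonconvergent, diverged,
#'   mean_iterations, mean_runtime_s) and \code{settings}.
#' @export
misconvergence_benchmark <- function(fixture, algorithms = c("new", "lin_fast"),
                                     n_trials = 1000, cfg = icar_config(),
                                     spec = contrast_spec(),
                                     desired_ics = NULL, ref_quality = 0.9,
                                     match_threshold = 0.95,
                                     master_seed = 1) {
  stopifnot(all(algorithms %in% c("new", "lin_fast", "lu_original")))
  cfg$init <- "random"; cfg$seed <- NULL
  l <- nrow(fixture$sources)
  if (is.null(desired_ics)) desired_ics <- seq_len(l)
  wh <- whiten_signals(center_signals(signal_matrix(fixture$observations)),
                       rank_tol = cfg$rank_tol)
  Z <- wh$signals$data
  rows <- NULL
  for (d in desired_ics) {
    r <- make_reference(fixture$sources[d, ], ref_quality,
                        seed = master_seed + 1000L + d)
    for (alg in algorithms) {
      set.seed(master_seed + 131L * d + match(alg, c("new", "lin_fast", "lu_original")))
      acc <- mis <- neg <- int <- nonc <- div <- 0L
      iters <- 0; t0 <- proc.time()[["elapsed"]]
      if (n_trials > 0) for (tr in seq_len(n_trials)) {
        res <- switch(alg,
          new = extract_one(Z, r, cfg, spec, keep_traces = TRUE),
          lin_fast = extract_one_legacy(Z, r, cfg, spec, "lin_fast"),
          lu_original = extract_one_legacy(Z, r, cfg, spec, "lu_original"))
        cl <- classify_run(res, fixture, d, match_threshold)
        iters <- iters + res$iterations
        if (cl$label == "accurate") acc <- acc + 1L
        if (cl$label == "misconverged") mis <- mis + 1L
        if (cl$label == "nonconvergent") nonc <- nonc + 1L
        if (cl$label == "diverged") div <- div + 1L
        if (cl$negative_denominator) {
          neg <- neg + 1L
          if (cl$label == "misconverged") int <- int + 1L
        }
      }
      rt <- proc.time()[["elapsed"]] - t0
      rows <- rbind(rows, data.frame(
        algorithm = alg, desired = d, n_trials = n_trials,
        accurate = acc, misconverged = mis, negative_denominator = neg,
        intersection = int, nonconvergent = nonc, diverged = div,
        mean_iterations = if (n_trials > 0) iters / n_trials else NA_real_,
        mean_runtime_s = if (n_trials > 0) rt / n_trials else NA_real_))
    }
  }
  structure(list(counts = rows,
                 settings = list(n_trials = n_trials, xi = cfg$xi,
                                 eta = cfg$eta, ref_quality = ref_quality,
                                 match_threshold = match_threshold,
                                 master_seed = master_seed)),
            class = "icar_benchmark")
}

#' @export
print.icar_benchmark <- function(x, ...) {
  cat("icar_benchmark (", x$settings$n_trials, "trials per IC, xi =",
      x$settings$xi, ")\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Predict the attraction basin of an initial weight vector
#'
#' For a noise-free mixture and the fourth-moment contrast, the
#' unconstrained negentropy ascent in the transformed coordinates
#' q (q_i ~ correlation of the output with source i) grows the components
#' whose kurtosis sign matches the sign of the current mixture kurtosis
#' kappa(y) = sum_i kappa_i q_i^4, at relative rates |kappa_i| q_i^2.
#' The predicted destination is therefore the argmax of |kappa_i| q_i^2
#' over the sources with sign(kappa_i) = sign(kappa(y)) (all sources if
#' none matches). Sources with |kappa| near zero (noise) get vanishing
#' weight -- their basin is negligible.
#'
#' @param fixture noise-free \code{\link{mixture_fixture}}.
#' @param z whitened observations.
#' @param w unit initial weight vector.
#' @return Index of the predicted source, or \code{"boundary"} when the
#'   top two scores tie within 1e-9.
#' @export
basin_indicator <- function(fixture, z, w) {
  q <- transformed_coordinates(fixture, z, w)
  q <- q / sqrt(sum(q^2))
  kap <- apply(fixture$sources, 1, excess_kurtosis)
  ky <- sum(kap * q^4)
  score <- abs(kap) * q^2
  cand <- which(sign(kap) == sign(ky))
  if (length(cand) == 0L) cand <- seq_along(kap)
  sc <- score[cand]
  ord <- order(sc, decreasing = TRUE)
  if (length(sc) > 1 && sc[ord[1]] - sc[ord[2]] < 1e-9) return("boundary")
  cand[ord[1]]
}

#' Gradient-following oracle for the attraction basin
#'
#' Brute-force reference implementation: small-step projected gradient
#' ascent of the squared-kurtosis contrast on the actual whitened samples,
#' run to convergence from \code{w}; returns the index of the source the
#' ascent lands on. Used to validate \code{\link{basin_indicator}}.
#'
#' @param fixture noise-free \code{\link{mixture_fixture}}.
#' @param z whitened observations.
#' @param w unit initial weight vector.
#' @param step0 initial step size.
#' @param iters maximum ascent iterations.
#' @return Source index.
#' @export
basin_oracle <- function(fixture, z, w, step0 = 0.05, iters = 3000) {
  Z <- if (inherits(z, "signal_matrix")) z$data else as.matrix(z)
  n <- ncol(Z)
  w2 <- w
  for (i in seq_len(iters)) {
    y <- drop(crossprod(w2, Z))
    kk <- mean(y^4) - 3
    gr <- 8 * kk * drop(Z %*% (y^3)) / n
    gr <- gr - sum(gr * w2) * w2
    ng <- sqrt(sum(gr^2))
    if (ng < 1e-10) break
    st <- step0 / (1 + i / 1000)
    w2 <- w2 + st * gr / ng * min(1, ng)
    w2 <- w2 / sqrt(sum(w2^2))
    if (i %% 50 == 0) {
      q <- transformed_coordinates(fixture, Z, w2)
      if (max(abs(q)) > 0.995) break
    }
  }
  q <- transformed_coordinates(fixture, Z, w2)
  which.max(abs(q))
}
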