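# Suboptimal-trajectory variability: discretize the continuous system by
# zero-order hold at a rise-time-derived sampling step, perturb the optimal
# control input over many iterations, roll the discrete dynamics
#   xbar(t+1) = Abar xbar(t) + Bbar ubar(t)
# forward, and summarise the per-timestep trajectory cloud by PCA.

#' Discretize a stable continuous-time system by zero-order hold
#'
#' The sampling time is tied to the system's own timescale:
#' `Ts = RT / 10` where `RT = ln(9) / max_i |Re(lambda_i(A))|` is the
#' 10-to-90 percent rise time of the fastest first-order mode. Then
#' `Abar = e^(A Ts)` and `Bbar = (integral_0^Ts e^(A s) ds) B`, computed as
#' `A^{-1}(Abar - I) B` for invertible `A` and through the augmented
#' block-exponential otherwise.
#'
#' @param sysmat a strictly stable `system_matrix`.
#' @param B input matrix (default identity).
#' @return An object of class `discrete_system`: `Abar`, `Bbar`, `Ts`,
#'   `rise_time`, `n`, `m`.
#' @export
discretize <- function(sysmat, B = NULL) {
  stopifnot(inherits(sysmat, "system_matrix"))
  A <- sysmat$A
  n <- nrow(A)
  if (is.null(B)) B <- diag(n)
  B <- as.matrix(B)
  if (nrow(B) != n) stop("B row dimension must match A")
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) stop("discretize requires a strictly stable A")
  rise_time <- log(9) / max(abs(Re(ev)))
  Ts <- rise_time / 10
  Abar <- expm_mat(A * Ts)
  Bbar <- tryCatch(solve(A, Abar - diag(n)) %*% B, error = function(e) {
    # augmented exponential: expm([[A, B], [0, 0]] * Ts) top-right block
    m <- ncol(B)
    blk <- rbind(cbind(A, B), matrix(0, m, n + m))
    expm_mat(blk * Ts)[1:n, (n + 1):(n + m), drop = FALSE]
  })
  structure(list(Abar = Abar, Bbar = Bbar, Ts = Ts, rise_time = rise_time,
                 n = n, m = ncol(B)),
            class = "discrete_system")
}

#' @export
print.discrete_system <- function(x, ...) {
  cat(sprintf("<discrete_system> n=%d, m=%d, Ts=%.4g (rise time %.4g)\n",
              x$n, x$m, x$Ts, x$rise_time))
  invisible(x)
}

# Zero-order-hold resample of the continuous optimal input at the Ts grid:
# value at each sampling instant, held over the following step.
resample_input <- function(transition, Ts) {
  Th <- transition$spec$horizon
  K <- max(1L, floor(Th / Ts + 1e-9))
  tk <- (seq_len(K) - 1L) * Ts
  u <- transition$u_traj
  tt <- transition$times
  idx <- pmin(findInterval(tk + 1e-12, tt), length(tt))
  u[, idx, drop = FALSE]
}

#' Generate an ensemble of perturbed (suboptimal) trajectories
#'
#' Resamples the optimal control input on the `Ts` grid (zero-order hold),
#' then for each of `n_iter` iterations adds i.i.d. Gaussian noise with
#' standard deviation `sigma * RMS(u*)` to every input sample and rolls the
#' discrete dynamics forward from `x0`. Perturbing the input (rather than
#' the states) keeps every suboptimal trajectory consistent with the
#' dynamics. Fully determined by `seed`.
#'
#' @param dsys a [discretize()]d system matching the transition's dynamics.
#' @param transition a `transition_result` from [optimal_control()].
#' @param sigma nonnegative relative perturbation scale (default 0.05,
#'   "subtle" relative to the RMS of the optimal input).
#' @param n_iter number of perturbed trajectories (study default 200).
#' @param seed integer RNG seed.
#' @return An object of class `suboptimal_ensemble`: `optimal_discrete`
#'   (n x (K+1), columns are timesteps 0..K), `perturbed`
#'   (array n x (K+1) x n_iter), `sigma`, `Ts`, `K`, `u_rms`.
#' @export
perturb_trajectories <- function(dsys, transition, sigma = 0.05,
                                 n_iter = 200L, seed = NULL) {
  stopifnot(inherits(dsys, "discrete_system"),
            inherits(transition, "transition_result"))
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  n <- dsys$n
  if (nrow(transition$x_traj) != n) stop("transition dimension mismatch")
  ubar <- resample_input(transition, dsys$Ts)
  if (nrow(ubar) != dsys$m) stop("input channel mismatch between dsys and transition")
  K <- ncol(ubar)
  x0 <- transition$x_traj[, 1L]
  u_rms <- sqrt(mean(transition$u_traj^2))
  # Per-sample sd is sigma * RMS(u*) at the canonical sampling step
  # Ts = rise_time / 10, and scales as 1/sqrt(Ts) away from it, so the
  # perturbation emulates input white noise of fixed intensity and the
  # induced trajectory dispersion does not depend on the Ts choice.
  ts_canon <- dsys$rise_time / 10
  noise_sd <- sigma * u_rms * sqrt(ts_canon / dsys$Ts)

  roll <- function(noise) {
    # noise: m x K x J array (J trajectories at once)
    J <- dim(noise)[3L]
    X <- array(0, c(n, K + 1L, J))
    cur <- matrix(x0, n, J)
    X[, 1L, ] <- cur
    for (k in seq_len(K)) {
      uk <- matrix(ubar[, k], dsys$m, J) + noise[, k, ]
      cur <- dsys$Abar %*% cur + dsys$Bbar %*% uk
      X[, k + 1L, ] <- cur
    }
    X
  }
  optimal_discrete <- roll(array(0, c(dsys$m, K, 1L)))[, , 1L, drop = FALSE]
  dim(optimal_discrete) <- c(n, K + 1L)
  perturbed <- with_seed(seed, {
    noise <- array(stats::rnorm(dsys$m * K * n_iter, sd = noise_sd),
                   c(dsys$m, K, n_iter))
    roll(noise)
  })
  structure(list(optimal_discrete = optimal_discrete, perturbed = perturbed,
                 sigma = sigma, Ts = dsys$Ts, K = K, u_rms = u_rms),
            class = "suboptimal_ensemble")
}

#' Summarise an ensemble's deviation from the optimal trajectory
#'
#' At each timestep the cloud of perturbed state points is reduced by PCA;
#' the fraction of variance on the first principal component is recorded,
#' the perturbed points and the optimal point are projected onto PC1, and
#' `d(t)` is the maximum absolute projected distance of any suboptimal point
#' from the optimal one. The scalar summary is
#' `100 * mean_t d(t) / ||x*(t)||_2`, a scale-free percentage. A degenerate
#' (all-identical) cloud has deviation 0 and PC1 variance fraction 1 by
#' convention.
#'
#' @param ensemble a [perturb_trajectories()] ensemble with `>= 2`
#'   trajectories.
#' @return A list: `deviation_percent` (scalar), `pc1_variance_fraction`
#'   (per-timestep trace, length K+1), `max_projected_distance`
#'   (per-timestep `d(t)`).
#' @export
deviation_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "suboptimal_ensemble"))
  J <- dim(ensemble$perturbed)[3L]
  if (J < 2L) stop("need at least 2 perturbed trajectories")
  nt <- ncol(ensemble$optimal_discrete)
  pc1_frac <- numeric(nt)
  dmax <- numeric(nt)
  ratio <- numeric(nt)
  degenerate <- FALSE
  for (k in seq_len(nt)) {
    pts <- t(ensemble$perturbed[, k, ])          # J x n cloud
    ctr <- colMeans(pts)
    cc <- sweep(pts, 2L, ctr)
    cv <- crossprod(cc) / (J - 1)
    tot <- sum(diag(cv))
    if (tot < 1e-300) {
      # degenerate cloud: no principal direction; deviation 0, PC1 = 1
      pc1_frac[k] <- 1
      dmax[k] <- 0
      if (k > 1L) degenerate <- TRUE   # all trajectories share x0 at k = 1
    } else {
      eg <- eigen(cv, symmetric = TRUE)
      pc1_frac[k] <- eg$values[1L] / tot
      w1 <- eg$vectors[, 1L]
      proj <- cc %*% w1
      proj_opt <- sum((ensemble$optimal_discrete[, k] - ctr) * w1)
      dmax[k] <- max(abs(proj - proj_opt))
    }
    xnorm <- sqrt(sum(ensemble$optimal_discrete[, k]^2))
    ratio[k] <- if (dmax[k] == 0) 0 else dmax[k] / max(xnorm, 1e-12)
  }
  if (degenerate && ensemble$sigma > 0) {
    ctl_log("degenerate suboptimal cloud at one or more timesteps")
  }
  list(deviation_percent = 100 * mean(ratio),
       pc1_variance_fraction = pc1_frac,
       max_projected_distance = dmax)
}

#' Repeated perturbation analysis
#'
#' Runs [perturb_trajectories()] + [deviation_summary()] `n_repeat` times
#' with independent seeded substreams (study defaults: 10 repeats of 200
#' iterations = 2000 suboptimal trajectories per subject).
#'
#' @inheritParams perturb_trajectories
#' @param n_repeat number of repeats (default 10).
#' @return A list: `deviation_percent` (length `n_repeat`),
#'   `mean_deviation`, `mean_pc1_variance_fraction` (scalar, averaged over
#'   repeats and timesteps), `sigma`, `n_iter`, `n_repeat`.
#' @export
repeat_analysis <- function(dsys, transition, sigma = 0.05, n_iter = 200L,
                            n_repeat = 10L, seed = NULL) {
  n_repeat <- as.integer(n_repeat)
  if (n_repeat < 1L) stop("n_repeat must be >= 1")
  dev <- numeric(n_repeat)
  pc1 <- numeric(n_repeat)
  for (r in seq_len(n_repeat)) {
    sr <- if (is.null(seed)) NULL else seed_substream(seed, "suboptimal", r)
    ens <- perturb_trajectories(dsys, transition, sigma = sigma,
                                n_iter = n_iter, seed = sr)
    s <- deviation_summary(ens)
    dev[r] <- s$deviation_percent
    pc1[r] <- mean(s$pc1_variance_fraction)
  }
  list(deviation_percent = dev, mean_deviation = mean(dev),
       mean_pc1_variance_fraction = mean(pc1),
       sigma = sigma, n_iter = n_iter, n_repeat = n_repeat)
}
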