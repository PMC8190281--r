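# Finite-horizon optimal control on a stabilized connectome: transition
# energy, state stability, and per-node control impact.
#
# The transition problem minimizes the Hamiltonian cost
#   H(p, x, u, t) = x'x + rho u'u + p'(A x + B u)
# whose first-order conditions give u* = -B'p/(2 rho) and the linear
# two-point boundary value problem on the augmented state (x, p):
#   d/dt [x; p] = [[A, -BB'/(2 rho)], [-2I, -A']] [x; p].
# The solver takes the matrix exponential of the augmented matrix, solves a
# dense linear system for the initial costate p(0) such that x(T) = xT, and
# propagates (x, p) on a uniform time grid.

#' Specify a state transition for the optimal control solver
#'
#' @param x0 numeric source state (length n).
#' @param xT numeric target state (length n).
#' @param horizon positive control horizon `T` (arbitrary time units,
#'   default 1, the convention of the network-control literature).
#' @param rho positive energy-penalty weight; the study default is 1.
#' @param control_set indices of the regions allowed to inject control input
#'   (columns of `B = I[, control_set]`). Default `NULL` means all regions,
#'   i.e. `B = I`.
#' @param nsteps number of uniform time-grid points (default 1001).
#' @return An object of class `transition_spec`.
#' @export
transition_spec <- function(x0, xT, horizon = 1, rho = 1,
                            control_set = NULL, nsteps = 1001L) {
  x0 <- as.numeric(x0); xT <- as.numeric(xT)
  if (length(x0) != length(xT)) stop("x0 and xT must have equal length")
  if (anyNA(x0) || anyNA(xT)) stop("states contain NA")
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  nsteps <- as.integer(nsteps)
  if (nsteps < 2L) stop("nsteps must be >= 2")
  if (!is.null(control_set)) {
    control_set <- as.integer(control_set)
    if (length(control_set) == 0L || anyDuplicated(control_set) ||
        any(control_set < 1L) || any(control_set > length(x0))) {
      stop("control_set must be unique indices in 1..n")
    }
  }
  structure(list(x0 = x0, xT = xT, horizon = horizon, rho = rho,
                 control_set = control_set, nsteps = nsteps),
            class = "transition_spec")
}

# Input matrix B for a spec at dimension n.
input_matrix <- function(n, control_set = NULL) {
  if (is.null(control_set)) diag(n) else diag(n)[, control_set, drop = FALSE]
}

#' Solve the finite-horizon optimal control problem
#'
#' Drives the linear system `dx/dt = A x + B u` from `x0` to `xT` over the
#' horizon, minimizing the integrated cost `x'x + rho u'u`. Returns the
#' optimal control and state trajectories, the per-node control energies
#' `E_k = integral of u_k(t)^2 dt` (composite trapezoid on the grid), their
#' sum `E`, `log10(E)`, and the relative endpoint miss.
#'
#' @param sysmat a `system_matrix` from [stabilize()] (any square dynamics
#'   matrix object with field `A` works).
#' @param spec a [transition_spec()] whose states match `sysmat$n`.
#' @param boundary_tol maximum admissible relative endpoint error
#'   `||x(T) - xT|| / max(||xT||, 1)`; default `1e-4`. Exceeding it is an
#'   error carrying the condition number of the boundary block.
#' @return An object of class `transition_result` with fields `u_traj`
#'   (m x nsteps), `x_traj`, `costate_traj` (n x nsteps), `times`,
#'   `nodal_energy` (length m), `total_energy`, `log_energy`, `cost`
#'   (the full Hamiltonian objective, trapezoid on the grid),
#'   `boundary_error`, `condition_number`, and the solver inputs.
#' @export
optimal_control <- function(sysmat, spec, boundary_tol = 1e-4) {
  stopifnot(inherits(sysmat, "system_matrix"), inherits(spec, "transition_spec"))
  A <- sysmat$A
  n <- nrow(A)
  if (length(spec$x0) != n) {
    stop(sprintf("state length %d does not match system dimension %d",
                 length(spec$x0), n))
  }
  B <- input_matrix(n, spec$control_set)
  m <- ncol(B)
  rho <- spec$rho
  Th <- spec$horizon
  nsteps <- spec$nsteps

  BBt <- B %*% t(B)
  aug <- rbind(cbind(A, -BBt / (2 * rho)),
               cbind(-2 * diag(n), -t(A)))

  ET <- expm_mat(aug * Th)
  E11 <- ET[1:n, 1:n, drop = FALSE]
  E12 <- ET[1:n, (n + 1):(2 * n), drop = FALSE]
  kappa <- kappa(E12, exact = FALSE)
  rhs <- spec$xT - E11 %*% spec$x0
  p0 <- tryCatch(solve(E12, rhs), error = function(e) {
    stop(sprintf("singular boundary solve (condition number %.3g): %s",
                 kappa, conditionMessage(e)))
  })

  dt <- Th / (nsteps - 1)
  Edt <- expm_mat(aug * dt)
  z <- matrix(0, 2 * n, nsteps)
  z[, 1L] <- c(spec$x0, p0)
  for (k in seq_len(nsteps - 1L)) z[, k + 1L] <- Edt %*% z[, k]

  x_traj <- z[1:n, , drop = FALSE]
  p_traj <- z[(n + 1):(2 * n), , drop = FALSE]
  u_traj <- -(t(B) %*% p_traj) / (2 * rho)

  nodal_energy <- trapz(u_traj^2, dt)
  total_energy <- sum(nodal_energy)
  cost <- trapz(colSums(x_traj^2) + rho * colSums(u_traj^2), dt)
  boundary_error <- sqrt(sum((x_traj[, nsteps] - spec$xT)^2)) /
    max(sqrt(sum(spec$xT^2)), 1)
  if (boundary_error > boundary_tol) {
    stop(sprintf(paste0("boundary error %.3g exceeds tolerance %.3g ",
                        "(n=%d, horizon=%.3g, condition number %.3g)"),
                 boundary_error, boundary_tol, n, Th, kappa))
  }

  rn <- sysmat$labels %||% rownames(A)
  names(nodal_energy) <- if (is.null(spec$control_set)) rn else rn[spec$control_set]
  structure(list(u_traj = u_traj, x_traj = x_traj, costate_traj = p_traj,
                 times = seq(0, Th, length.out = nsteps),
                 nodal_energy = nodal_energy,
                 total_energy = total_energy,
                 log_energy = log10(total_energy),
                 cost = cost,
                 boundary_error = boundary_error,
                 condition_number = kappa,
                 spec = spec),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf("<transition_result> E = %.6g (log10 %.4g), cost = %.6g, boundary err %.2g\n",
              x$total_energy, x$log_energy, x$cost, x$boundary_error))
  invisible(x)
}

#' Stability of a brain state
#'
#' The maintenance energy of a state is the optimal control energy of the
#' self-transition `x -> x`; stability is its inverse log-energy,
#' `S = 1 / log10(E_maintain)`. States whose maintenance energy is `<= 1`
#' make `S` undefined or sign-flipped, and are flagged `valid = FALSE`
#' (stability `NA`) rather than silently reported; cohort statistics drop
#' them with a logged count.
#'
#' @param sysmat a `system_matrix`.
#' @param x the state to maintain (length n).
#' @inheritParams transition_spec
#' @param ... passed to [optimal_control()].
#' @return An object of class `stability_result`: `maintain_energy`,
#'   `stability`, `valid`, plus the underlying `transition_result`.
#' @export
state_stability <- function(sysmat, x, horizon = 1, rho = 1,
                            nsteps = 1001L, ...) {
  spec <- transition_spec(x, x, horizon = horizon, rho = rho, nsteps = nsteps)
  res <- optimal_control(sysmat, spec, ...)
  e <- res$total_energy
  valid <- is.finite(e) && e > 1
  structure(list(maintain_energy = e,
                 stability = if (valid) 1 / log10(e) else NA_real_,
                 valid = valid,
                 transition = res),
            class = "stability_result")
}

#' Per-node control impact by leave-one-out removal
#'
#' For each region i, removes row/column i from the dynamics matrix, entry i
#' from both boundary states, and region i's control channel (with `B = I`
#' a removed region can neither steer nor be steered), re-solves the
#' transition, and reports `impact_i = E_removed(i) - E_baseline`: positive
#' impact means the region's presence lowers the energy demand of the
#' transition. Removals whose boundary problem fails are flagged `NA` with a
#' logged message.
#'
#' @param sysmat a `system_matrix` with `n >= 3`.
#' @param spec a [transition_spec()].
#' @param ... passed to [optimal_control()].
#' @return An object of class `impact_result`: `impact` (length n, named),
#'   `baseline_energy`, `labels`.
#' @export
control_impact <- function(sysmat, spec, ...) {
  stopifnot(inherits(sysmat, "system_matrix"))
  n <- sysmat$n
  if (n < 3L) stop("control impact needs n >= 3")
  baseline <- optimal_control(sysmat, spec, ...)$total_energy
  impact <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    Ai <- sysmat$A[keep, keep, drop = FALSE]
    cs <- spec$control_set
    cs_i <- if (is.null(cs)) NULL else match(setdiff(cs, i), keep)
    if (!is.null(cs_i) && length(cs_i) == 0L) {
      ctl_log(sprintf("node %d removal leaves no control channel; impact NA", i))
      next
    }
    sub <- structure(list(A = Ai, spectral_bound = NA_real_,
                          normalization = sysmat$normalization,
                          labels = sysmat$labels[keep], n = n - 1L),
                     class = "system_matrix")
    spec_i <- transition_spec(spec$x0[keep], spec$xT[keep],
                              horizon = spec$horizon, rho = spec$rho,
                              control_set = cs_i, nsteps = spec$nsteps)
    ei <- tryCatch(optimal_control(sub, spec_i, ...)$total_energy,
                   error = function(e) {
                     ctl_log(sprintf("node %d removal unsolvable: %s",
                                     i, conditionMessage(e)))
                     NA_real_
                   })
    impact[i] <- if (is.na(ei)) NA_real_ else ei - baseline
  }
  names(impact) <- sysmat$labels
  structure(list(impact = impact, baseline_energy = baseline,
                 labels = sysmat$labels),
            class = "impact_result")
}

#' Top control-impact regions
#'
#' Ranks regions by absolute control impact (descending, ties broken by node
#' index ascending) and returns the top `ceiling(fraction * n)`.
#'
#' @param result an `impact_result` from [control_impact()].
#' @param fraction fraction of regions to keep, in `(0, 1]`; 0.2 reproduces
#'   the "20 percent highest control impact" selection.
#' @return A data.frame with columns `rank`, `node`, `label`, `impact`.
#' @export
top_impact_nodes <- function(result, fraction = 0.2) {
  stopifnot(inherits(result, "impact_result"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  n <- length(result$impact)
  ord <- order(-abs(result$impact), seq_len(n))
  k <- ceiling(fraction * n)
  sel <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), node = sel,
             label = result$labels[sel],
             impact = unname(result$impact[sel]))
}
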