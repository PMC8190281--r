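# Cohort-level drivers: run the control solver, the perturbation analysis,
# and the statistical battery over a cohort object. Used by the command
# line entry points and directly from R.

#' Compute energies and stabilities for every subject of a cohort
#'
#' Per subject: stabilizes the connectome, computes the maintenance energy
#' and stability of both condition states, and the optimal transition
#' energy both ways (0-back to 2-back and back). Subjects whose maintenance
#' energy is `<= 1` keep `valid_* = FALSE` with `stability_* = NA`; they
#' are reported, never dropped silently.
#'
#' @param cohort a `cohort` object.
#' @param horizon,rho,nsteps solver parameters (see [transition_spec()]).
#' @param scheme stabilization scheme (see [stabilize()]).
#' @param impact also compute per-node control impact of the 0-to-2
#'   transition (expensive: n + 1 solves per subject). Default `FALSE`.
#' @return A list: `table` (one row per subject: energies, log energies,
#'   stabilities, validity flags, boundary errors), `nodal_energy_02`
#'   (subjects x regions matrix of per-node energies for the 0-to-2
#'   transition), and `impact` (subjects x regions, when requested).
#' @export
cohort_energies <- function(cohort, horizon = 1, rho = 1, nsteps = 1001L,
                            scheme = "spectral", impact = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  S <- nrow(cohort$table)
  n <- nrow(cohort$states0)
  res <- data.frame(subject_id = cohort$table$subject_id,
                    stringsAsFactors = FALSE)
  num <- function() rep(NA_real_, S)
  res$maintain_energy_0 <- num(); res$maintain_energy_2 <- num()
  res$stability_0 <- num(); res$stability_2 <- num()
  res$valid_0 <- res$valid_2 <- rep(NA, S)
  res$energy_02 <- num(); res$energy_20 <- num()
  res$log_energy_02 <- num(); res$log_energy_20 <- num()
  res$boundary_error_02 <- num(); res$boundary_error_20 <- num()
  nodal <- matrix(NA_real_, S, n)
  imp <- if (impact) matrix(NA_real_, S, n) else NULL
  for (i in seq_len(S)) {
    A <- stabilize(cohort$connectomes[[i]], scheme = scheme)
    x0 <- cohort$states0[, i]; x2 <- cohort$states2[, i]
    s0 <- state_stability(A, x0, horizon = horizon, rho = rho, nsteps = nsteps)
    s2 <- state_stability(A, x2, horizon = horizon, rho = rho, nsteps = nsteps)
    t02 <- optimal_control(A, transition_spec(x0, x2, horizon, rho, nsteps = nsteps))
    t20 <- optimal_control(A, transition_spec(x2, x0, horizon, rho, nsteps = nsteps))
    res$maintain_energy_0[i] <- s0$maintain_energy
    res$maintain_energy_2[i] <- s2$maintain_energy
    res$stability_0[i] <- s0$stability
    res$stability_2[i] <- s2$stability
    res$valid_0[i] <- s0$valid; res$valid_2[i] <- s2$valid
    res$energy_02[i] <- t02$total_energy
    res$energy_20[i] <- t20$total_energy
    res$log_energy_02[i] <- t02$log_energy
    res$log_energy_20[i] <- t20$log_energy
    res$boundary_error_02[i] <- t02$boundary_error
    res$boundary_error_20[i] <- t20$boundary_error
    nodal[i, ] <- t02$nodal_energy
    if (impact) {
      imp[i, ] <- control_impact(A, t02$spec)$impact
    }
  }
  n_invalid <- sum(!res$valid_0) + sum(!res$valid_2)
  if (n_invalid > 0) ctl_log(sprintf("%d invalid stability values flagged", n_invalid))
  list(table = res, nodal_energy_02 = nodal, impact = imp)
}

#' Suboptimal-trajectory analysis over a cohort
#'
#' For each subject, solves the 0-to-2 transition, discretizes the system
#' at its rise-time-derived sampling step, and runs [repeat_analysis()]
#' (default 10 repeats of 200 perturbed trajectories).
#'
#' @inheritParams cohort_energies
#' @param sigma relative perturbation scale.
#' @param n_iter,n_repeat ensemble sizes.
#' @param seed master seed; subjects get independent substreams.
#' @return A tidy data.frame: `subject_id`, `repeat`, `sigma`,
#'   `deviation_percent`, `mean_pc1_variance_fraction`.
#' @export
cohort_suboptimal <- function(cohort, horizon = 1, rho = 1, nsteps = 1001L,
                              scheme = "spectral", sigma = 0.05,
                              n_iter = 200L, n_repeat = 10L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  S <- nrow(cohort$table)
  rows <- vector("list", S)
  for (i in seq_len(S)) {
    A <- stabilize(cohort$connectomes[[i]], scheme = scheme)
    tr <- optimal_control(A, transition_spec(cohort$states0[, i],
                                             cohort$states2[, i],
                                             horizon, rho, nsteps = nsteps))
    dsys <- discretize(A)
    ra <- repeat_analysis(dsys, tr, sigma = sigma, n_iter = n_iter,
                          n_repeat = n_repeat,
                          seed = seed_substream(seed, "subject", i))
    rows[[i]] <- data.frame(subject_id = cohort$table$subject_id[i],
                            rep = seq_len(n_repeat),
                            sigma = sigma,
                            deviation_percent = ra$deviation_percent,
                            mean_pc1_variance_fraction = ra$mean_pc1_variance_fraction,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the cohort statistical battery
#'
#' Applies the study's test structure to pipeline outputs: the
#' within-subject stability and transition-energy contrasts (difference
#' score ANCOVA, age and sex plus the relevant activity covariate), the
#' between-group contrasts on 2-back stability and 0-to-2 log energy when
#' two groups are present (adding tSNR), and the gene-score regressions
#' (D1 on stability, D2 on log transition energy with stabilities as
#' additional nuisance covariates). Invalid stabilities enter as `NA` and
#' are dropped listwise with a log entry.
#'
#' @param cohort a `cohort` object.
#' @param energies output of [cohort_energies()].
#' @return A data.frame of test rows (see [rm_anova_2level()]).
#' @export
cohort_stats <- function(cohort, energies) {
  tab <- cbind(build_covariates(cohort),
               energies$table[, setdiff(names(energies$table), "subject_id")])
  out <- list()
  out$stab <- within_effect(
    rm_anova_2level(tab, c("stability_0", "stability_2"),
                    covariates = c("age", "sex", "mean_activity_0",
                                   "mean_activity_2")),
    "stability: 0-back vs 2-back")
  out$ener <- within_effect(
    rm_anova_2level(tab, c("log_energy_02", "log_energy_20"),
                    covariates = c("age", "sex", "activity_difference")),
    "log energy: 0->2 vs 2->0")
  if (length(unique(tab$group)) == 2L) {
    out$g_stab <- within_effect(
      covariate_regression(tab, "stability_2", "group",
                           covariates = c("age", "sex", "tsnr",
                                          "mean_activity_2")),
      "group effect on 2-back stability")
    out$g_ener <- within_effect(
      covariate_regression(tab, "log_energy_02", "group",
                           covariates = c("age", "sex", "tsnr",
                                          "activity_difference")),
      "group effect on 0->2 log energy")
  }
  if ("d1_score" %in% names(tab)) {
    out$d1 <- within_effect(
      covariate_regression(tab, "stability_2", "d1_score",
                           covariates = c("age", "sex", "mean_activity_2")),
      "D1 score -> 2-back stability")
    out$d2 <- within_effect(
      covariate_regression(tab, "log_energy_02", "d2_score",
                           covariates = c("age", "sex", "activity_difference",
                                          "stability_0", "stability_2")),
      "D2 score -> 0->2 log energy")
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

within_effect <- function(df, name) {
  df$analysis <- name
  df[, c("analysis", setdiff(names(df), "analysis"))]
}
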