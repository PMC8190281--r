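# Synthetic data generator: modular FA-weighted connectomes, paired task
# activation states, topology-degrading rewiring, and full cohorts with
# injected group and gene-score effects. Stands in for fMRI/DTI/genetic
# inputs that are not publicly deposited, so that every pipeline stage is
# testable end to end.

#' Generate a modular FA-weighted synthetic connectome
#'
#' Nodes are split evenly over `n_modules` communities; each node pair is
#' connected with probability `density` and connected pairs draw a weight
#' from a Beta distribution bounded in `[0, 1]` (mimicking fractional
#' anisotropy), with a higher mean inside modules (`intra_weight`) than
#' between them (`inter_weight`).
#'
#' @param n_nodes number of regions (default 374, the atlas size emulated).
#' @param n_modules number of communities (default 8).
#' @param intra_weight mean within-module edge weight in `(0,1)`
#'   (default 0.5).
#' @param inter_weight mean between-module edge weight in `(0,1)`
#'   (default 0.2).
#' @param density edge probability in `(0, 1]` (default 0.25).
#' @param concentration Beta concentration (shape1 + shape2) of the weight
#'   distribution (default 10).
#' @param seed integer RNG seed.
#' @return A [connectome()] carrying the module assignment as attribute
#'   `"modules"` (integer vector, length `n_nodes`).
#' @export
make_connectome <- function(n_nodes = 374L, n_modules = 8L,
                            intra_weight = 0.5, inter_weight = 0.2,
                            density = 0.25, concentration = 10,
                            seed = NULL) {
  n_nodes <- as.integer(n_nodes); n_modules <- as.integer(n_modules)
  if (n_nodes < 2L) stop("n_nodes must be >= 2")
  if (n_modules < 1L || n_modules > n_nodes) {
    stop("incompatible module count: need 1 <= n_modules <= n_nodes")
  }
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  stopifnot(intra_weight > 0, intra_weight < 1,
            inter_weight > 0, inter_weight < 1)
  modules <- rep(seq_len(n_modules), length.out = n_nodes)
  w <- with_seed(seed, {
    np <- n_nodes * (n_nodes - 1L) / 2L
    same_mat <- outer(modules, modules, `==`)
    same <- same_mat[upper.tri(same_mat)]
    present <- stats::runif(np) < density
    mu <- ifelse(same, intra_weight, inter_weight)
    vals <- stats::rbeta(np, mu * concentration, (1 - mu) * concentration)
    ut <- ifelse(present, vals, 0)
    m <- matrix(0, n_nodes, n_nodes)
    m[upper.tri(m)] <- ut
    m + t(m)
  })
  cn <- connectome(w)
  attr(cn, "modules") <- modules
  cn
}

#' Generate a paired 0-back / 2-back activation state
#'
#' Emulates region-averaged GLM beta patterns for the two task conditions.
#' Both states share a module-grouped node ordering drawn from
#' `support_seed`: the 0-back (attention/motor control) state loads the
#' first `ceil(spread0 * n)` nodes of that ordering (a focal pattern,
#' essentially one module at the default spread), the 2-back (working
#' memory) state loads the first `ceil(spread2 * n)` nodes (a nested,
#' higher-amplitude, more distributed pattern covering several modules).
#' Supported nodes get per-node loading multipliers `U(0.8, 1.2)` shared
#' between conditions; i.i.d. Gaussian noise with sd `noise_sd` is added.
#'
#' @param cn a [connectome()] (module attribute used when present).
#' @param amp0,amp2 condition amplitudes; by default the working-memory
#'   state is stronger (`amp2 = 2 >= amp0 = 1`).
#' @param spread0,spread2 active fractions of nodes, in `(0, 1]`
#'   (defaults 0.1 and 0.4).
#' @param noise_sd additive Gaussian noise sd (default 0.1).
#' @param seed seed for the noise draws.
#' @param support_seed seed for the support ordering and loadings
#'   (defaults to `seed`); sharing it across subjects yields a common
#'   spatial template with subject-specific noise.
#' @return A list: `state0`, `state2` (length-n vectors), `mean0`, `mean2`
#'   (their region-wise means), `support0`, `support2` (node indices).
#' @export
make_state_pair <- function(cn, amp0 = 1, amp2 = 2,
                            spread0 = 0.1, spread2 = 0.4,
                            noise_sd = 0.1, seed = NULL,
                            support_seed = seed) {
  stopifnot(inherits(cn, "connectome"))
  if (spread0 <= 0 || spread0 > 1 || spread2 <= 0 || spread2 > 1) {
    stop("spread must be in (0, 1]")
  }
  if (amp0 <= 0 || amp2 <= 0) stop("amplitudes must be > 0")
  n <- cn$n
  modules <- attr(cn, "modules") %||% rep(1L, n)
  tmpl <- with_seed(support_seed, {
    mod_order <- sample(unique(modules))
    ord <- unlist(lapply(mod_order, function(m) {
      idx <- which(modules == m)
      idx[sample.int(length(idx))]
    }), use.names = FALSE)
    list(ord = ord, load = stats::runif(n, 0.8, 1.2))
  })
  build <- function(amp, spread, noise) {
    k <- ceiling(spread * n)
    x <- numeric(n)
    sup <- tmpl$ord[seq_len(k)]
    x[sup] <- amp * tmpl$load[seq_len(k)]
    list(state = x + noise, support = sort(sup))
  }
  noises <- with_seed(seed, list(n0 = stats::rnorm(n, sd = noise_sd),
                                 n2 = stats::rnorm(n, sd = noise_sd)))
  s0 <- build(amp0, spread0, noises$n0)
  s2 <- build(amp2, spread2, noises$n2)
  list(state0 = s0$state, state2 = s2$state,
       mean0 = mean(s0$state), mean2 = mean(s2$state),
       support0 = s0$support, support2 = s2$support)
}

#' Degrade a connectome by weight-preserving random rewiring
#'
#' Randomly swaps the weights of a fraction of the existing edges with
#' uniformly chosen node-pair slots (occupied or empty), preserving
#' symmetry, the zero diagonal, the exact multiset of weights, and hence
#' total strength. Moving within-module weight onto random pairs erodes the
#' modular topology without changing the weight distribution, emulating the
#' subtle connectome randomization associated with the patient group.
#'
#' @param cn a [connectome()].
#' @param rewire_fraction fraction of (nonzero) edges whose weight is
#'   relocated, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A [connectome()]; the module attribute of the input (describing
#'   the original, now partially destroyed, community structure) is kept.
#' @export
degrade_connectome <- function(cn, rewire_fraction, seed = NULL) {
  stopifnot(inherits(cn, "connectome"))
  if (!is.numeric(rewire_fraction) || rewire_fraction < 0 || rewire_fraction > 1) {
    stop("rewire_fraction must be in [0, 1]")
  }
  w <- cn$weights
  ut_idx <- which(upper.tri(w))
  vals <- w[ut_idx]
  nz <- which(vals > 0)
  k <- round(rewire_fraction * length(nz))
  if (k > 0L) {
    with_seed(seed, {
      src <- sample(nz, k)
      tgt <- sample.int(length(vals), k)
      for (j in seq_len(k)) {
        tmp <- vals[src[j]]
        vals[src[j]] <- vals[tgt[j]]
        vals[tgt[j]] <- tmp
      }
    })
    w[ut_idx] <- vals
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  }
  out <- connectome(w, labels = cn$labels)
  attr(out, "modules") <- attr(cn, "modules")
  out
}

#' Generate a synthetic two-group cohort
#'
#' Builds a control/patient cohort with the structure the cohort analyses
#' assume: every subject gets a connectome, a 0-back/2-back state pair
#' sharing a cohort-level spatial template, demographic covariates drawn
#' from ranges matching the study population, and standardized D1/D2
#' polygenic-proxy scores. Effects are injected as follows:
#'
#' * `stability_d` — every subject's 2-back state is rescaled around its
#'   own mean by a lognormal dispersion factor (sd `sigma_amp` on the log
#'   scale); patients' log dispersion is shifted upward by
#'   `stability_d * sigma_amp`. A more dispersed pattern with the same
#'   global mean costs more energy to maintain, so 2-back stability drops
#'   by about `stability_d` control-group standard deviations — and,
#'   because the scaling is mean-preserving, the effect survives the
#'   mean-activity covariate adjustment the statistics apply (the
#'   dispersion latent is the dominant variance source by design).
#' * `energy_d` — patients' connectomes are degraded with
#'   `rewire_fraction = rewire_per_d * energy_d` (capped at 1 with a
#'   warning), raising transition energy through topology rather than
#'   weight loss.
#' * `gene_slopes` — `d1_score` is generated anti-correlated with the
#'   subject's 2-back amplitude latent (so it predicts stability
#'   positively), `d2_score` anti-correlated with the amplitude-difference
#'   latent (so it predicts transition energy negatively); both are
#'   standardized within the cohort.
#'
#' @param n_controls,n_patients group sizes (defaults 80 and 24, matching
#'   the matched-control / patient comparison).
#' @param effect_sizes list with `stability_d`, `energy_d` (Cohen's d
#'   scale) and `gene_slopes` (named `d1`, `d2`, correlations in `[0, 1)`).
#' @param n_nodes,n_modules connectome size (defaults 374 regions,
#'   8 modules).
#' @param amp0,amp2,spread0,spread2,noise_sd state-pair parameters, see
#'   [make_state_pair()].
#' @param sigma_amp between-subject sd of the log amplitude latents
#'   (default 0.35).
#' @param rewire_per_d rewiring fraction injected per unit of `energy_d`
#'   (default 0.25).
#' @param seed master seed; every subject draws from named substreams.
#' @param out_dir optional directory; when given, all cohort files are
#'   written via [write_cohort()].
#' @return An object of class `cohort`: `table` (data.frame with
#'   subject_id, group, age, sex, tsnr, d1_score, d2_score), `states0` /
#'   `states2` (n_nodes x n_subjects matrices), `connectomes` (list),
#'   `params`.
#' @export
make_cohort <- function(n_controls = 80L, n_patients = 24L,
                        effect_sizes = list(stability_d = 0.8,
                                            energy_d = 0.5,
                                            gene_slopes = c(d1 = 0.3, d2 = 0.3)),
                        n_nodes = 374L, n_modules = 8L,
                        amp0 = 1, amp2 = 2, spread0 = 0.1, spread2 = 0.4,
                        noise_sd = 0.05, sigma_amp = 0.35,
                        rewire_per_d = 0.25,
                        seed = 1L, out_dir = NULL) {
  n_controls <- as.integer(n_controls); n_patients <- as.integer(n_patients)
  if (n_controls < 2L || n_patients < 2L) stop("group sizes must be >= 2")
  sd_stab <- effect_sizes$stability_d %||% 0
  sd_ener <- effect_sizes$energy_d %||% 0
  slopes <- effect_sizes$gene_slopes %||% c(d1 = 0, d2 = 0)
  if (!all(is.finite(c(sd_stab, sd_ener, slopes)))) {
    stop("effect sizes must be finite")
  }
  rewire <- rewire_per_d * sd_ener
  if (rewire > 1) {
    warning(sprintf("energy_d = %.3g needs rewire_fraction %.3g > 1; capped at 1 (achieved effect will be smaller)",
                    sd_ener, rewire))
    rewire <- 1
  }
  S <- n_controls + n_patients
  group <- c(rep("control", n_controls), rep("patient", n_patients))
  support_seed <- seed_substream(seed, "support")

  cov_draws <- with_seed(seed_substream(seed, "covariates"), {
    list(age = pmin(pmax(round(stats::rnorm(S, 33, 11)), 18), 65),
         sex = stats::rbinom(S, 1L, 0.5),
         tsnr = stats::rnorm(S, ifelse(group == "control", 5.52, 5.26), 0.49),
         z0 = stats::rnorm(S, 0, sigma_amp),
         z2 = stats::rnorm(S, 0, sigma_amp),
         eps1 = stats::rnorm(S), eps2 = stats::rnorm(S))
  })
  # subject-level log dispersion latents; the patient shift enters the
  # 2-back dispersion only, orthogonal to mean activity by construction
  z2 <- cov_draws$z2 + ifelse(group == "patient", sd_stab * sigma_amp, 0)
  gam0_i <- exp(cov_draws$z0)
  gam2_i <- exp(z2)

  s1 <- max(min(slopes[["d1"]], 0.99), 0)
  s2 <- max(min(slopes[["d2"]], 0.99), 0)
  l2 <- cov_draws$z2 / sigma_amp
  ld <- (cov_draws$z2 - cov_draws$z0) / (sqrt(2) * sigma_amp)
  d1 <- as.numeric(scale(-s1 * l2 + sqrt(1 - s1^2) * cov_draws$eps1))
  d2 <- as.numeric(scale(-s2 * ld + sqrt(1 - s2^2) * cov_draws$eps2))

  connectomes <- vector("list", S)
  states0 <- matrix(0, n_nodes, S)
  states2 <- matrix(0, n_nodes, S)
  for (i in seq_len(S)) {
    cn <- make_connectome(n_nodes, n_modules,
                          seed = seed_substream(seed, "connectome", i))
    if (group[i] == "patient" && rewire > 0) {
      cn <- degrade_connectome(cn, rewire,
                               seed = seed_substream(seed, "rewire", i))
    }
    sp <- make_state_pair(cn, amp0 = amp0, amp2 = amp2,
                          spread0 = spread0, spread2 = spread2,
                          noise_sd = noise_sd,
                          seed = seed_substream(seed, "state", i),
                          support_seed = support_seed)
    connectomes[[i]] <- cn
    # mean-preserving dispersion scaling around the subject's own mean
    states0[, i] <- sp$mean0 + gam0_i[i] * (sp$state0 - sp$mean0)
    states2[, i] <- sp$mean2 + gam2_i[i] * (sp$state2 - sp$mean2)
  }
  tab <- data.frame(subject_id = sprintf("S%03d", seq_len(S)),
                    group = group,
                    age = cov_draws$age,
                    sex = cov_draws$sex,
                    tsnr = cov_draws$tsnr,
                    d1_score = d1, d2_score = d2,
                    stringsAsFactors = FALSE)
  out <- structure(list(table = tab, states0 = states0, states2 = states2,
                        connectomes = connectomes,
                        params = list(n_controls = n_controls,
                                      n_patients = n_patients,
                                      effect_sizes = effect_sizes,
                                      n_nodes = n_nodes, n_modules = n_modules,
                                      amp0 = amp0, amp2 = amp2,
                                      spread0 = spread0, spread2 = spread2,
                                      noise_sd = noise_sd,
                                      sigma_amp = sigma_amp,
                                      rewire_per_d = rewire_per_d,
                                      rewire_fraction = rewire,
                                      seed = seed)),
                   class = "cohort")
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d controls + %d patients, %d regions\n",
              x$params$n_controls, x$params$n_patients, x$params$n_nodes))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per subject: a connectome CSV and one CSV per condition state; plus a
#' covariate table and a JSON parameter file. A `manifest.json` lists every
#' written file (3 per subject + 2) with its md5 checksum.
#'
#' @param cohort a [make_cohort()] object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest as a data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    ctl_log("created output directory ", dir)
  }
  files <- character(0)
  S <- nrow(cohort$table)
  for (i in seq_len(S)) {
    id <- cohort$table$subject_id[i]
    fc <- file.path(dir, paste0(id, "_connectome.csv"))
    write_connectome(cohort$connectomes[[i]], fc)
    f0 <- file.path(dir, paste0(id, "_state0.csv"))
    f2 <- file.path(dir, paste0(id, "_state2.csv"))
    labs <- cohort$connectomes[[i]]$labels
    writeLines(c("region,value",
                 sprintf("%s,%.17g", labs, cohort$states0[, i])), f0)
    writeLines(c("region,value",
                 sprintf("%s,%.17g", labs, cohort$states2[, i])), f2)
    files <- c(files, fc, f0, f2)
  }
  fcov <- file.path(dir, "covariates.csv")
  utils::write.csv(cohort$table, fcov, row.names = FALSE)
  fpar <- file.path(dir, "cohort_config.json")
  par_out <- cohort$params
  par_out$effect_sizes$gene_slopes <- as.list(par_out$effect_sizes$gene_slopes)
  jsonlite::write_json(par_out, fpar, auto_unbox = TRUE, digits = NA)
  files <- c(files, fcov, fpar)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows")
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding the cohort files.
#' @return A `cohort` object (params restored from the JSON config).
#' @export
load_cohort <- function(dir) {
  fcov <- file.path(dir, "covariates.csv")
  if (!file.exists(fcov)) stop("no covariates.csv in ", dir)
  tab <- utils::read.csv(fcov, stringsAsFactors = FALSE)
  params <- jsonlite::read_json(file.path(dir, "cohort_config.json"),
                                simplifyVector = TRUE)
  S <- nrow(tab)
  connectomes <- vector("list", S)
  states0 <- states2 <- NULL
  for (i in seq_len(S)) {
    id <- tab$subject_id[i]
    connectomes[[i]] <- load_connectome(file.path(dir, paste0(id, "_connectome.csv")))
    s0 <- utils::read.csv(file.path(dir, paste0(id, "_state0.csv")))$value
    s2 <- utils::read.csv(file.path(dir, paste0(id, "_state2.csv")))$value
    if (is.null(states0)) {
      states0 <- matrix(0, length(s0), S)
      states2 <- matrix(0, length(s2), S)
    }
    states0[, i] <- s0
    states2[, i] <- s2
  }
  structure(list(table = tab, states0 = states0, states2 = states2,
                 connectomes = connectomes, params = params),
            class = "cohort")
}
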