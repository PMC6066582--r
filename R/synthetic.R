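#' Simulation scenario for synthetic connectome cohorts
#'
#' Describes a multi-site cohort whose healthy functional connectomes share
#' a low-rank latent structure (the reusable "prior" an offline-learned
#' prototype can exploit), with a disease group differing on a small
#' planted set of edges, plus additive site and demographic confounds. All
#' effects are applied on the Fisher-z scale and mapped through z -> r
#' (tanh), so features stay valid correlations in (-1, 1).
#'
#' @param n_rois number of ROIs (default 90, giving 4,005 edge features).
#' @param n_per_group target-site subjects per group (default 30).
#' @param n_sites number of target sites (default 2).
#' @param n_offline healthy offline-corpus size (default 400).
#' @param n_offline_sites sites the offline corpus is spread over
#'   (default 8).
#' @param latent_dim dimension of the shared healthy latent structure
#'   (default 10).
#' @param latent_sd total latent standard deviation per edge, z units
#'   (default 0.4).
#' @param n_planted number of planted discriminative edges (default 10);
#'   ignored when `planted_edges` is given.
#' @param planted_edges optional two-column matrix of (i, j) ROI pairs,
#'   i < j, to plant the group effect on.
#' @param planted_mode how default planted edges are chosen.
#'   `"structured"` (default): the `n_planted` edges loading most strongly
#'   on the first latent factor, with the effect signed by the loading —
#'   the disease perturbs connections that participate in the shared
#'   healthy structure, which is the premise that makes an
#'   offline-learned representation transferable. `"random"`: uniformly
#'   random edges with a positive shift; such an effect is almost
#'   orthogonal to the latent structure and no reconstruction-driven
#'   encoder can retain it.
#' @param effect_size mean z-scale FC shift on planted edges in the disease
#'   group (default 0.6).
#' @param site_shift sd of per-site additive feature offsets, z units
#'   (default 0.1).
#' @param covariate_effects named list of z-scale coefficients:
#'   `age` (per year, age centered), `sex` (added for males),
#'   `handedness` (added for right-handers).
#' @param noise_sd independent edge noise sd, z units (default 0.25).
#' @param missing_rate fraction of missing handedness values (default 0.05).
#' @param seed integer seed.
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_rois = 90L, n_per_group = 30L, n_sites = 2L,
                         n_offline = 400L, n_offline_sites = 8L,
                         latent_dim = 10L, latent_sd = 0.4,
                         n_planted = 10L, planted_edges = NULL,
                         planted_mode = c("structured", "random"),
                         effect_size = 0.6, site_shift = 0.1,
                         covariate_effects = list(age = 0.01, sex = 0.1,
                                                  handedness = 0.05),
                         noise_sd = 0.25, missing_rate = 0.05, seed = 7L) {
  planted_mode <- match.arg(planted_mode)
  stopifnot(n_rois >= 3, n_per_group >= 1, n_sites >= 1, n_offline >= 1,
            latent_dim >= 1, effect_size >= 0, site_shift >= 0,
            noise_sd >= 0, missing_rate >= 0, missing_rate <= 1)
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    stopifnot(ncol(planted_edges) == 2,
              all(planted_edges[, 1] < planted_edges[, 2]),
              all(planted_edges >= 1), all(planted_edges <= n_rois),
              !anyDuplicated(planted_edges))
  }
  structure(list(n_rois = as.integer(n_rois),
                 n_per_group = as.integer(n_per_group),
                 n_sites = as.integer(n_sites),
                 n_offline = as.integer(n_offline),
                 n_offline_sites = as.integer(n_offline_sites),
                 latent_dim = as.integer(latent_dim), latent_sd = latent_sd,
                 n_planted = as.integer(n_planted),
                 planted_edges = planted_edges,
                 planted_mode = planted_mode,
                 effect_size = effect_size, site_shift = site_shift,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a synthetic connectome cohort
#'
#' Generates an offline healthy corpus plus a multi-site target cohort
#' (healthy `HC` vs disease `ASD`) of vectorized FC features. Healthy
#' edge values are `z = mu + Lambda u + site + covariates + noise` on the
#' Fisher-z scale (shared low-rank latent structure `Lambda u`); disease
#' subjects are additionally shifted by `effect_size` on the planted
#' edges; `r = tanh(z)`. Offline and target subjects live in disjoint
#' subject-id namespaces (`OFF_*`, `TGT_*`) and sites. Handedness values
#' are dropped at `missing_rate` to exercise covariate imputation. Fully
#' reproducible from `sc$seed`.
#'
#' @param sc a [sim_scenario()].
#' @return List with `dataset` (a [connectome_dataset()] covering offline
#'   and target subjects; column `cohort` of the covariates distinguishes
#'   them) and `truth` (planted (i, j) pairs, their edge indices,
#'   `effect_size`, `seed`).
#' @export
simulate_cohort <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  set.seed(sc$seed)
  n <- sc$n_rois
  F <- n * (n - 1) / 2
  pairs <- edge_pairs(n)

  # cohort-level structure, fixed per scenario draw
  mu <- stats::rnorm(F, 0.25, 0.2)
  Lambda <- matrix(stats::rnorm(F * sc$latent_dim,
                                sd = sc$latent_sd / sqrt(sc$latent_dim)),
                   F, sc$latent_dim)
  planted <- sc$planted_edges
  if (is.null(planted)) {
    idx <- if (identical(sc$planted_mode, "structured"))
      order(-abs(Lambda[, 1]))[seq_len(sc$n_planted)]
    else
      sample.int(F, sc$n_planted)
    planted <- pairs[idx, , drop = FALSE]
  } else {
    idx <- match(paste(planted[, 1], planted[, 2]),
                 paste(pairs[, 1], pairs[, 2]))
  }
  effect_sign <- if (is.null(sc$planted_edges) &&
                     identical(sc$planted_mode, "structured"))
    sign(Lambda[idx, 1]) else rep(1, length(idx))

  site_names <- c(paste0("OFF", seq_len(sc$n_offline_sites)),
                  paste0("TGT", seq_len(sc$n_sites)))
  site_eff <- matrix(stats::rnorm(length(site_names) * F,
                                  sd = sc$site_shift),
                     length(site_names), F,
                     dimnames = list(site_names, NULL))

  draw_subjects <- function(m, site, group, id_prefix) {
    u <- matrix(stats::rnorm(m * sc$latent_dim), m, sc$latent_dim)
    Z <- matrix(mu, m, F, byrow = TRUE) + u %*% t(Lambda) +
      matrix(stats::rnorm(m * F, sd = sc$noise_sd), m, F)
    Z <- Z + matrix(site_eff[site, ], m, F, byrow = TRUE)
    age <- round(stats::runif(m, 8, 30), 1)
    sex <- sample(c("M", "F"), m, replace = TRUE, prob = c(0.7, 0.3))
    hand <- sample(c("R", "L"), m, replace = TRUE, prob = c(0.9, 0.1))
    ce <- sc$covariate_effects
    Z <- Z + (age - 19) * (ce$age %||% 0) +
      (sex == "M") * (ce$sex %||% 0) +
      (hand == "R") * (ce$handedness %||% 0)
    if (group == "ASD")
      Z[, idx] <- Z[, idx] +
        matrix(sc$effect_size * effect_sign, m, length(idx), byrow = TRUE)
    if (any(abs(Z) > 18)) {   # tanh underflows to +/-1 beyond ~18
      warning("extreme z values clipped to keep correlations inside (-1, 1)")
      Z <- pmin(pmax(Z, -18), 18)
    }
    hand[stats::runif(m) < sc$missing_rate] <- NA
    list(features = tanh(Z),
         covariates = data.frame(site = site, age = age, sex = sex,
                                 handedness = hand,
                                 cohort = if (group == "HC" &&
                                              startsWith(site, "OFF"))
                                   "offline" else "target",
                                 stringsAsFactors = FALSE),
         labels = rep(group, m),
         ids = sprintf("%s_%s_%s_%03d", id_prefix, site, group, seq_len(m)))
  }

  blocks <- list()
  per_off <- diff(round(seq(0, sc$n_offline,
                            length.out = sc$n_offline_sites + 1)))
  for (s in seq_len(sc$n_offline_sites))
    if (per_off[s] > 0)
      blocks[[length(blocks) + 1]] <-
        draw_subjects(per_off[s], paste0("OFF", s), "HC", "OFF")
  for (s in seq_len(sc$n_sites)) {
    blocks[[length(blocks) + 1]] <-
      draw_subjects(sc$n_per_group, paste0("TGT", s), "HC", "TGT")
    blocks[[length(blocks) + 1]] <-
      draw_subjects(sc$n_per_group, paste0("TGT", s), "ASD", "TGT")
  }

  ds <- connectome_dataset(
    do.call(rbind, lapply(blocks, `[[`, "features")),
    unlist(lapply(blocks, `[[`, "labels")),
    do.call(rbind, lapply(blocks, `[[`, "covariates")),
    unlist(lapply(blocks, `[[`, "ids")), n)
  list(dataset = ds,
       truth = list(planted_edges = planted, edge_index = idx,
                    effect_sign = effect_sign,
                    effect_size = sc$effect_size, seed = sc$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a simulated dataset into offline corpus and target cohort
#'
#' The offline corpus contains only healthy subjects from non-target
#' sites; the target cohort contains all subjects from target sites. The
#' two are disjoint by subject id by construction.
#'
#' @param ds a [connectome_dataset()] produced by [simulate_cohort()].
#' @return List with `offline` and `target` datasets.
#' @export
split_offline_target <- function(ds) {
  off <- ds$covariates$cohort == "offline"
  list(offline = subset_dataset(ds, off),
       target = subset_dataset(ds, !off))
}

#' Simulate ROI time series with a target correlation structure
#'
#' Draws `T` multivariate Gaussian timepoints whose population correlation
#' is `Sigma`; the empirical FC converges to `Sigma` as `T` grows.
#' Non-positive-definite inputs are repaired to the nearest positive
#' definite matrix (eigenvalue clipping) with a warning.
#'
#' @param Sigma symmetric target correlation matrix.
#' @param T number of timepoints. @param seed integer seed.
#' @param subject_id id for the returned series.
#' @return A [roi_timeseries()].
#' @export
simulate_timeseries <- function(Sigma, T, seed = 1L, subject_id = "sim") {
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == ncol(Sigma),
            max(abs(Sigma - t(Sigma))) < 1e-8)
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    warning("Sigma is not positive definite; repaired by eigenvalue clipping")
    vals <- pmax(ev$values, 1e-8)
    Sigma <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(Sigma))
    Sigma <- Sigma / tcrossprod(d)
  }
  set.seed(seed)
  X <- MASS::mvrnorm(T, mu = rep(0, nrow(Sigma)), Sigma = Sigma)
  roi_timeseries(subject_id, X)
}
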