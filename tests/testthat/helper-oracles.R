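# Shared oracles and fixtures, independent of the implementation paths
# they check.

# Central finite-difference gradient of a scalar function.
numeric_gradient <- function(fn, w, h = 1e-6) {
  vapply(seq_along(w), function(i) {
    e <- numeric(length(w)); e[i] <- h
    (fn(w + e) - fn(w - e)) / (2 * h)
  }, numeric(1))
}

max_rel_err <- function(analytic, numeric, floor = 1e-8) {
  max(abs(analytic - numeric) / pmax(abs(numeric), floor))
}

# Brute-force AUC: count positive-negative pairs, ties worth 1/2.
brute_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Flatten an AE parameter list in the packing order used internally.
flat_ae <- function(ae) c(ae$W1, ae$b1, ae$W2, ae$b2)

# A small fast scenario for end-to-end tests (12 ROIs -> 66 edges).
tiny_scenario <- function(seed = 7, ...) {
  sim_scenario(n_rois = 12, n_per_group = 10, n_sites = 1, n_offline = 40,
               n_offline_sites = 2, latent_dim = 4, n_planted = 5,
               seed = seed, ...)
}

tiny_hp <- function(...) {
  args <- list(...)
  defaults <- list(layer_sizes = c(8, 8, 8), max_epochs = 40, seed = 1)
  do.call(hyperparams, utils::modifyList(defaults, args))
}

# Constructed multi-site dataset with known covariate structure.
make_covariate_dataset <- function(m = 40, n_rois = 8, seed = 1,
                                   age_coef = 0, site_delta = 0,
                                   noise_sd = 0) {
  set.seed(seed)
  F <- n_rois * (n_rois - 1) / 2
  site <- rep(c("A", "B"), each = m / 2)
  age <- round(runif(m, 10, 40), 1)
  sex <- sample(c("M", "F"), m, replace = TRUE)
  hand <- sample(c("R", "L"), m, replace = TRUE, prob = c(0.8, 0.2))
  base <- matrix(rnorm(m * F, 0, 0.1), m, F)
  feats <- base + age_coef * age +
    site_delta * ifelse(site == "A", 1, -1) +
    matrix(rnorm(m * F, 0, noise_sd), m, F)
  connectome_dataset(feats, rep(c("HC", "ASD"), m / 2),
                     data.frame(site = site, age = age, sex = sex,
                                handedness = hand,
                                stringsAsFactors = FALSE),
                     sprintf("S%03d", seq_len(m)), n_rois)
}
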