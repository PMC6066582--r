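test_that("Pearson FC matrices match a per-pair oracle", {
  set.seed(1)
  X <- matrix(rnorm(200 * 3), 200, 3)
  M <- compute_fc_matrix(roi_timeseries("s1", X))
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_true(all(M >= -1 & M <= 1))
  # textbook covariance/sigma oracle per pair
  for (i in 1:2) for (j in (i + 1):3) {
    num <- mean((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j])))
    den <- sqrt(mean((X[, i] - mean(X[, i]))^2) *
                  mean((X[, j] - mean(X[, j]))^2))
    expect_equal(unname(M[i, j]), num / den, tolerance = 1e-12)
  }
  # identical series -> 1, negated series -> -1
  Y <- cbind(X[, 1], X[, 1], -X[, 1])
  M2 <- suppressWarnings(compute_fc_matrix(roi_timeseries("s2", Y)))
  expect_equal(unname(M2[1, 2]), 1)
  expect_equal(unname(M2[1, 3]), -1)
  # zero-variance ROI zeroed with warning
  Z <- cbind(X[, 1:2], 0)
  expect_warning(M3 <- compute_fc_matrix(roi_timeseries("s3", Z)),
                 "zero-variance")
  expect_equal(unname(M3[3, 1:2]), c(0, 0))
  expect_error(roi_timeseries("s4", X[1:2, ]), "3 timepoints")
})

test_that("vectorization is row-major upper triangle with exact inverse", {
  M3 <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3)
  expect_equal(vectorize_fc(M3), c(.1, .2, .3))   # (1,2),(1,3),(2,3)
  expect_equal(nrow(edge_pairs(4)), 6)
  expect_equal(edge_pairs(4)[, "i"], c(1, 1, 1, 2, 2, 3))
  expect_equal(edge_pairs(4)[, "j"], c(2, 3, 4, 3, 4, 4))

  # a 90-ROI matrix yields exactly 4005 features
  set.seed(2)
  A <- matrix(rnorm(90 * 90), 90); S <- (A + t(A)) / 2; diag(S) <- 1
  v <- vectorize_fc(S)
  expect_length(v, 4005)
  expect_equal(devectorize_fc(v, 90), S)

  # order check on an asymmetric-free 4x4 case
  S4 <- devectorize_fc(1:6 / 10, 4)
  expect_equal(S4[1, 2], 0.1); expect_equal(S4[1, 4], 0.3)
  expect_equal(S4[2, 3], 0.4); expect_equal(S4[3, 4], 0.6)

  Asym <- S; Asym[1, 2] <- Asym[1, 2] + 1e-3
  expect_error(vectorize_fc(Asym), "symmetric")
})

test_that("null-confound data passes through harmonization essentially unchanged", {
  ds <- make_covariate_dataset(m = 60, noise_sd = 0)
  out <- suppressMessages(site_bias_correct(ds))
  # features were built independent of all covariates (per-feature sd 0.1);
  # only OLS shrinkage noise of order sd*sqrt(k/n) remains
  expect_lt(max(abs(out$features - ds$features)), 0.25)
  expect_lt(mean(abs(out$features - ds$features)), 0.05)
  expect_identical(out$covariates, ds$covariates)   # retained for audit
})

test_that("harmonization removes a constructed age effect", {
  ds <- make_covariate_dataset(m = 50, age_coef = 2, noise_sd = 0)
  out <- suppressMessages(site_bias_correct(ds))
  # refit-and-check oracle: post-correction age slope is ~0 per feature
  for (f in c(1, 5, 20)) {
    fit <- lm(out$features[, f] ~ factor(ds$covariates$site) +
                ds$covariates$age)
    expect_lt(abs(coef(fit)[["ds$covariates$age"]]), 1e-8)
  }
})

test_that("harmonization equalizes constructed site means", {
  ds <- make_covariate_dataset(m = 40, site_delta = 0.5, noise_sd = 0)
  out <- suppressMessages(site_bias_correct(ds))
  ma <- colMeans(out$features[ds$covariates$site == "A", ])
  mb <- colMeans(out$features[ds$covariates$site == "B", ])
  expect_lt(max(abs(ma - mb)), 1e-10)
})

test_that("refitting the confound model after correction yields zero coefficients", {
  ds <- make_covariate_dataset(m = 60, age_coef = 1.5, site_delta = 0.4,
                               noise_sd = 0)
  out <- suppressMessages(site_bias_correct(ds))
  dat <- data.frame(site = factor(ds$covariates$site),
                    age = ds$covariates$age,
                    sex = factor(ds$covariates$sex),
                    handedness = factor(ds$covariates$handedness))
  Xd <- model.matrix(~ site + age + sex + handedness, dat)
  B <- qr.coef(qr(Xd), out$features)
  expect_lt(max(abs(B[-1, ])), 1e-8)
})

test_that("harmonization is idempotent on noiseless constructions", {
  ds <- make_covariate_dataset(m = 40, age_coef = 1, site_delta = 0.3,
                               noise_sd = 0)
  once <- suppressMessages(site_bias_correct(ds))
  twice <- suppressMessages(site_bias_correct(once))
  expect_lt(max(abs(twice$features - once$features)), 1e-10)
})

test_that("missing covariates are imputed with cohort mode/mean", {
  ds <- make_covariate_dataset(m = 40)
  ds$covariates$handedness[c(3, 9)] <- NA
  ds$covariates$age[5] <- NA
  expect_message(out <- site_bias_correct(ds), "imputed")
  log <- attr(out, "correction_log")
  expect_equal(unname(log$n_imputed[c("age", "handedness")]), c(1L, 2L))
})

test_that("aliased covariate columns are dropped with a warning", {
  ds <- make_covariate_dataset(m = 40)
  ds$covariates$sex <- "M"                 # single-sex cohort
  expect_warning(out <- suppressMessages(site_bias_correct(ds)),
                 "dropped")
  expect_s3_class(out, "connectome_dataset")
  expect_error(suppressMessages(
    site_bias_correct(subset_dataset(ds, ds$covariates$site == "A"))),
    "2 sites")
})

test_that("feature/phenotype tables and FC matrix files round-trip", {
  dir <- withr::local_tempdir()
  ds <- make_covariate_dataset(m = 10)
  fp <- file.path(dir, "features.tsv")
  pp <- file.path(dir, "phenotype.tsv")
  write_feature_table(ds$subject_ids, ds$features, fp)
  write_phenotype(data.frame(subject_id = ds$subject_ids,
                             site = ds$covariates$site, group = ds$labels,
                             age = ds$covariates$age,
                             sex = ds$covariates$sex,
                             handedness = ds$covariates$handedness), pp)
  back <- load_dataset(fp, pp)
  expect_equal(unname(back$features), unname(ds$features), tolerance = 1e-12)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$n_rois, ds$n_rois)

  M <- devectorize_fc(runif(28, -1, 1), 8)
  mp <- file.path(dir, "subj1.txt")
  write.table(M, mp, row.names = FALSE, col.names = FALSE)
  expect_equal(read_fc_matrix(mp), M, tolerance = 1e-12)
})
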