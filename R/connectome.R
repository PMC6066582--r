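#' ROI time series container
#'
#' @param subject_id character scalar.
#' @param data numeric matrix, timepoints x ROIs (T >= 3).
#' @param roi_names optional character vector of ROI names.
#' @return An object of class `"roi_timeseries"`.
#' @export
roi_timeseries <- function(subject_id, data, roi_names = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 3) stop("at least 3 timepoints are required")
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(data)))
  stopifnot(length(roi_names) == ncol(data))
  structure(list(subject_id = as.character(subject_id), data = data,
                 roi_names = as.character(roi_names)),
            class = "roi_timeseries")
}

#' Pearson functional-connectivity matrix
#'
#' Pairwise Pearson correlation between ROI time series (e.g. BOLD
#' signals), giving a symmetric adjacency matrix with unit diagonal.
#' Zero-variance ROIs yield undefined correlations; their entries are set
#' to 0 with a warning.
#'
#' @param ts a [roi_timeseries()].
#' @return Symmetric n x n correlation matrix, entries in \[-1, 1\],
#'   dimnames set to the ROI names.
#' @export
compute_fc_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$data, 2L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  M <- suppressWarnings(stats::cor(ts$data))
  if (any(flat)) {
    warning("zero-variance ROI(s) ",
            paste(ts$roi_names[flat], collapse = ", "),
            ": correlations set to 0")
    M[flat, ] <- 0
    M[, flat] <- 0
  }
  diag(M) <- 1
  dimnames(M) <- list(ts$roi_names, ts$roi_names)
  M
}

#' Vectorize / devectorize a symmetric FC matrix
#'
#' `vectorize_fc` extracts the strict upper triangle in row-major order —
#' pairs (1,2), (1,3), ..., (1,n), (2,3), ... — giving `n(n-1)/2` features
#' (4,005 for the 90-region AAL parcellation). `devectorize_fc` is its
#' inverse, restoring the symmetric matrix with unit diagonal.
#'
#' @param M symmetric numeric matrix (asymmetry beyond `tol` is an error).
#' @param tol symmetry tolerance (default `1e-8`).
#' @return For `vectorize_fc`, a numeric vector of length `n(n-1)/2`.
#' @export
vectorize_fc <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > tol)
    stop("vectorize_fc: matrix is not symmetric within tolerance ", tol)
  t(M)[lower.tri(M)]
}

#' @rdname vectorize_fc
#' @param v feature vector of length `n(n-1)/2`. @param n matrix dimension.
#' @export
devectorize_fc <- function(v, n) {
  if (length(v) != n * (n - 1) / 2)
    stop("devectorize_fc: expected length ", n * (n - 1) / 2,
         ", got ", length(v))
  B <- matrix(0, n, n)
  B[lower.tri(B)] <- v          # column-major lower = row-major upper of t(B)
  M <- t(B) + B
  diag(M) <- 1
  M
}

#' Row-major upper-triangle index pairs
#'
#' The (i, j) ROI pairs, i < j, in the order used by [vectorize_fc()].
#' Indices are 1-based, matching AAL-style region numbering in reports.
#'
#' @param n number of ROIs.
#' @return Two-column integer matrix with `n(n-1)/2` rows.
#' @export
edge_pairs <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  cbind(i = i, j = j)
}

#' Connectome dataset container
#'
#' Holds vectorized FC features for a cohort together with labels and
#' covariates.
#'
#' @param features subjects x `n_rois*(n_rois-1)/2` numeric matrix of FC
#'   weights.
#' @param labels per-subject class labels (character/factor).
#' @param covariates data.frame with columns `site`, `age`, `sex`,
#'   `handedness` (missing values allowed); extra columns are kept.
#' @param subject_ids unique subject identifiers.
#' @param n_rois number of ROIs the features were derived from.
#' @return An object of class `"connectome_dataset"`.
#' @export
connectome_dataset <- function(features, labels, covariates, subject_ids,
                               n_rois) {
  features <- as.matrix(features)
  n_rois <- as.integer(n_rois)
  if (ncol(features) != n_rois * (n_rois - 1) / 2)
    stop("feature count ", ncol(features), " does not match n_rois = ",
         n_rois, " (expected ", n_rois * (n_rois - 1) / 2, ")")
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  stopifnot(nrow(features) == length(subject_ids),
            length(labels) == length(subject_ids),
            nrow(covariates) == length(subject_ids),
            all(c("site", "age", "sex", "handedness") %in% names(covariates)))
  rownames(features) <- subject_ids
  structure(list(features = features, labels = as.character(labels),
                 covariates = as.data.frame(covariates),
                 subject_ids = subject_ids, n_rois = n_rois),
            class = "connectome_dataset")
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat("Connectome dataset:", length(x$subject_ids), "subjects,",
      ncol(x$features), "FC features (", x$n_rois, "ROIs ),",
      length(unique(x$covariates$site)), "site(s)\n")
  print(table(x$labels))
  invisible(x)
}

#' Subset a connectome dataset by subject index
#' @param ds a [connectome_dataset()]. @param idx integer or logical index.
#' @return A `"connectome_dataset"` restricted to the selected subjects.
#' @export
subset_dataset <- function(ds, idx) {
  connectome_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                     ds$covariates[idx, , drop = FALSE],
                     ds$subject_ids[idx], ds$n_rois)
}

impute_covariates <- function(cov) {
  n_imputed <- integer(0)
  for (col in c("site", "age", "sex", "handedness")) {
    x <- cov[[col]]
    miss <- is.na(x) | (is.character(x) & !is.na(x) & x == "")
    if (!any(miss)) next
    if (is.numeric(x)) {
      x[miss] <- mean(x[!miss])
    } else {
      tab <- table(x[!miss])
      x[miss] <- names(tab)[which.max(tab)]   # mode of the full cohort
    }
    cov[[col]] <- x
    n_imputed[col] <- sum(miss)
  }
  if (length(n_imputed))
    message("imputed missing covariate values: ",
            paste(names(n_imputed), n_imputed, sep = "=", collapse = ", "))
  attr(cov, "n_imputed") <- n_imputed
  cov
}

#' Multi-site confound harmonization
#'
#' Removes site and demographic confounds from every FC feature in two
#' steps, fit across the whole cohort:
#' \enumerate{
#'   \item Per feature, an ordinary-least-squares fit
#'     `y = b0 + b_site x_site + b_age age + b_sex sex + b_hand hand + e`
#'     (site, sex and handedness dummy-coded, reference level = first level
#'     alphabetically); the feature is replaced by `b0 + residual`.
#'   \item Per site, the difference between that site's mean value and the
#'     mean across all subjects is subtracted for the same feature.
#' }
#' Missing covariates are imputed first (categorical: cohort mode; numeric:
#' cohort mean) with a logged count. Rank-deficient designs (e.g. a
#' single-sex cohort) drop the aliased columns with a warning.
#'
#' @param ds a [connectome_dataset()] with at least 2 sites.
#' @param fit_on `"all"` (default; confound model fit on the full cohort)
#'   or `"train_only"` (fit on `fit_index`, applied to everyone, for
#'   leakage-sensitive workflows).
#' @param fit_index subject index used when `fit_on = "train_only"`.
#' @return The corrected `"connectome_dataset"` (covariates retained for
#'   audit), with attribute `"correction_log"` describing imputations,
#'   dropped columns and coding.
#' @export
site_bias_correct <- function(ds, fit_on = c("all", "train_only"),
                              fit_index = NULL) {
  fit_on <- match.arg(fit_on)
  stopifnot(inherits(ds, "connectome_dataset"))
  cov <- impute_covariates(ds$covariates)
  if (length(unique(cov$site)) < 2)
    stop("site_bias_correct requires at least 2 sites")

  dat <- data.frame(site = factor(cov$site), age = as.numeric(cov$age),
                    sex = factor(cov$sex), handedness = factor(cov$handedness))
  # single-level factors make model.matrix fail; recode as constants so the
  # aliased-column path below drops them instead
  for (col in c("site", "sex", "handedness"))
    if (nlevels(dat[[col]]) < 2) dat[[col]] <- 1
  Xd <- stats::model.matrix(~ site + age + sex + handedness, dat)

  rows <- if (fit_on == "train_only") {
    if (is.null(fit_index)) stop("fit_on = 'train_only' needs fit_index")
    fit_index
  } else seq_len(nrow(Xd))

  fit <- stats::lm.fit(Xd[rows, , drop = FALSE],
                       ds$features[rows, , drop = FALSE])
  B <- fit$coefficients
  if (is.null(dim(B))) B <- matrix(B, ncol = 1, dimnames = list(names(B)))
  dropped <- rownames(B)[apply(is.na(B), 1L, any)]
  if (length(dropped)) {
    warning("rank-deficient confound design; dropped column(s): ",
            paste(dropped, collapse = ", "))
    B[is.na(B)] <- 0
  }
  nonint <- setdiff(rownames(B), "(Intercept)")
  # replace y by b0 + residual, i.e. subtract the non-intercept fit
  Y <- ds$features - Xd[, nonint, drop = FALSE] %*% B[nonint, , drop = FALSE]

  # site-mean adjustment: shift each site's mean to the grand mean
  site <- factor(cov$site)
  site_means <- rowsum(Y, site) / as.vector(table(site))
  grand <- colMeans(Y)
  Y <- Y - (site_means[as.integer(site), , drop = FALSE] -
              matrix(grand, nrow(Y), ncol(Y), byrow = TRUE))

  out <- connectome_dataset(Y, ds$labels, ds$covariates, ds$subject_ids,
                            ds$n_rois)
  attr(out, "correction_log") <- list(
    n_imputed = attr(cov, "n_imputed"), dropped_columns = dropped,
    reference_levels = lapply(dat[c("site", "sex", "handedness")], function(x)
      if (is.factor(x)) levels(x)[1] else NA_character_),
    fit_on = fit_on)
  out
}

# ---- file I/O (plain-text formats) ----

#' Read and write connectome data files
#'
#' `read_fc_matrix` reads one whitespace- or comma-delimited n x n numeric
#' matrix (one subject per file; the file name stem is the subject id).
#' `read_feature_table`/`write_feature_table` handle a TSV with
#' `subject_id` in the first column and the `n(n-1)/2` vectorized FC
#' features in the remaining columns. `read_phenotype` reads a TSV with
#' columns `subject_id`, `site`, `group`, `age`, `sex`, `handedness`
#' (empty cells are missing).
#'
#' @param path file path.
#' @return `read_fc_matrix`: numeric matrix. `read_feature_table`: list
#'   with `subject_ids` and `features`. `read_phenotype`: data.frame.
#' @export
read_fc_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  M <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M)) stop("FC matrix in ", path, " is not square")
  M
}

#' @rdname read_fc_matrix
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c("character"))
  features <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(features) <- "double"
  list(subject_ids = tab[[1]], features = features)
}

#' @rdname read_fc_matrix
#' @param subject_ids character vector. @param features numeric matrix.
#' @export
write_feature_table <- function(subject_ids, features, path) {
  tab <- data.frame(subject_id = subject_ids, features,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("subject_id", paste0("fc", seq_len(ncol(features))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_fc_matrix
#' @export
read_phenotype <- function(path) {
  ph <- utils::read.delim(path, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "site", "group", "age", "sex", "handedness")
  missing_cols <- setdiff(need, names(ph))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  ph$age <- as.numeric(ph$age)
  ph
}

#' @rdname read_fc_matrix
#' @param ph phenotype data.frame.
#' @export
write_phenotype <- function(ph, path) {
  utils::write.table(ph, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Assemble a dataset from feature and phenotype tables
#'
#' Joins a vectorized FC feature table with a phenotype table by
#' `subject_id`.
#'
#' @param feature_path path to the feature TSV.
#' @param phenotype_path path to the phenotype TSV.
#' @param n_rois number of ROIs (inferred from the feature count when
#'   `NULL`).
#' @return A [connectome_dataset()].
#' @export
load_dataset <- function(feature_path, phenotype_path, n_rois = NULL) {
  ft <- read_feature_table(feature_path)
  ph <- read_phenotype(phenotype_path)
  if (!setequal(ft$subject_ids, ph$subject_id))
    stop("feature and phenotype tables cover different subjects")
  ph <- ph[match(ft$subject_ids, ph$subject_id), ]
  if (is.null(n_rois)) {
    n_rois <- (1 + sqrt(1 + 8 * ncol(ft$features))) / 2
    if (n_rois != round(n_rois))
      stop("feature count ", ncol(ft$features),
           " is not a valid n*(n-1)/2 edge count")
  }
  connectome_dataset(ft$features, ph$group,
                     ph[, c("site", "age", "sex", "handedness")],
                     ft$subject_ids, n_rois)
}
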