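#' Median-of-ratios size factors
#'
#' Library-size normalization: for each sample, the median over reference
#' features of the ratio between its count and the feature's geometric mean
#' across samples. Features with any zero count are excluded from the
#' reference (their geometric mean is zero). Factors are rescaled so their
#' geometric mean is exactly 1, making normalized counts scale-free.
#'
#' @param es An [expr_set()].
#' @return Named numeric vector of positive per-sample factors with
#'   geometric mean 1.
#' @export
size_factors <- function(es) {
  validate_expr_set(es)
  counts <- es$counts
  eligible <- rowSums(counts == 0) == 0
  if (!any(eligible)) {
    stop_input(paste0(
      "no feature has nonzero counts in every sample; ",
      "median-of-ratios is undefined (consider a pseudo-reference fallback)"))
  }
  elig <- counts[eligible, , drop = FALSE]
  ref <- exp(rowMeans(log(elig)))
  sf <- apply(elig / ref, 2, median)
  sf <- sf / geometric_mean(sf)
  sf
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-feature dispersion alpha from normalized counts, pooling variance
#' within groups: `alpha = (s2 - m) / m^2`, where `m` is the grand mean of
#' normalized counts and `s2` the pooled within-group variance. Estimates
#' below 1e-8 (including negative moment estimates, i.e. under-dispersed
#' features) are set to 0, the Poisson boundary.
#'
#' @param es An [expr_set()].
#' @param size_factors Per-sample factors; computed from `es` if omitted.
#' @return Named numeric vector of per-feature alpha (>= 0); `NA` for
#'   features with all-zero counts, which are flagged and excluded from
#'   downstream testing.
#' @export
estimate_dispersion <- function(es, size_factors = NULL) {
  sf <- size_factors %||% cernascreen::size_factors(es)
  groups <- es$samples$group
  if (any(table(groups) < 2)) stop_input("need >= 2 samples per group")
  norm <- normalized_counts(es, sf)
  m <- rowMeans(norm)
  ss <- 0
  df <- 0
  for (g in unique(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    gm <- rowMeans(sub)
    ss <- ss + rowSums((sub - gm)^2)
    df <- df + ncol(sub) - 1
  }
  s2 <- ss / df
  alpha <- (s2 - m) / m^2
  alpha[alpha < 1e-8] <- 0
  alpha[m == 0] <- NA_real_
  setNames(alpha, rownames(norm))
}

#' Moderate per-feature dispersions with a common-dispersion floor
#'
#' With three replicates per group the per-feature method-of-moments
#' dispersion is very noisy and frequently hits the Poisson boundary, which
#' makes the downstream Wald test anticonservative. This moderation floors
#' each feature's estimate at the median estimate of its RNA class (a
#' conservative variant of the common/tagwise-maximum rule used by
#' count-based DE tools): `alpha_i* = max(alpha_i, median_class(alpha))`.
#'
#' @param alpha Named per-feature dispersions from [estimate_dispersion()].
#' @param rna_class Per-feature class labels (same order); if `NULL` a
#'   single global median is used.
#' @return Moderated dispersions; `NA` entries are preserved.
#' @export
moderate_dispersion <- function(alpha, rna_class = NULL) {
  if (is.null(rna_class)) {
    return(pmax(alpha, median(alpha, na.rm = TRUE)))
  }
  med <- tapply(alpha, rna_class, median, na.rm = TRUE)
  pmax(alpha, unname(med[rna_class]))
}

#' Two-group negative-binomial Wald test
#'
#' For each feature, the base-10 log fold change of the cold group over the
#' control group on pseudocounted normalized group means,
#' `log10((m_cold + c) / (m_ctrl + c))`, and a Wald z statistic for the
#' natural log of that ratio with delta-method standard error
#' `SE^2 = (1/n1) (1/(m1+c) + alpha) + (1/n2) (1/(m2+c) + alpha)`,
#' referred to the standard normal (two-sided).
#'
#' @param es An [expr_set()].
#' @param size_factors Per-sample factors; computed from `es` if omitted.
#' @param dispersions Per-feature alpha; estimated from `es` if omitted.
#' @param pseudocount Positive constant added to each group mean
#'   (default 0.5) to guard zero means.
#' @return A tibble with one row per feature: `feature_id`, `rna_class`,
#'   `base_mean`, `log10_fc`, `se_log`, `p`. Features with undefined
#'   dispersion (all-zero counts) carry `NA` statistics.
#' @export
nb_wald_test <- function(es, size_factors = NULL, dispersions = NULL,
                         pseudocount = 0.5) {
  if (pseudocount <= 0) stop_input("pseudocount must be positive")
  sf <- size_factors %||% cernascreen::size_factors(es)
  groups <- es$samples$group
  if (length(unique(groups)) != 2) stop_input("exactly two groups required")
  n1 <- sum(groups == "control")
  n2 <- sum(groups == "cold")
  if (n1 == 0 || n2 == 0) stop_input("both groups need at least one sample")
  alpha <- dispersions %||% estimate_dispersion(es, sf)
  norm <- normalized_counts(es, sf)
  m1 <- rowMeans(norm[, groups == "control", drop = FALSE])
  m2 <- rowMeans(norm[, groups == "cold", drop = FALSE])
  c0 <- pseudocount
  lfc10 <- log10((m2 + c0) / (m1 + c0))
  se <- sqrt((1 / n1) * (1 / (m1 + c0) + alpha) +
             (1 / n2) * (1 / (m2 + c0) + alpha))
  z <- log((m2 + c0) / (m1 + c0)) / se
  p <- 2 * pnorm(-abs(z))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[is.na(alpha)] <- NA_real_
  tibble(feature_id = rownames(norm),
         rna_class = es$features$rna_class,
         base_mean = unname(rowMeans(norm)),
         log10_fc = unname(ifelse(is.na(alpha), NA_real_, lfc10)),
         se_log = unname(se), p = unname(p))
}

#' Default class-specific classification thresholds
#'
#' Volcano thresholds: `|log10 FC| >= 0.6` (about 4-fold) for every class,
#' raw p below 0.05 for mRNA and lncRNA and below 0.01 for miRNA and
#' circRNA.
#'
#' @return A list with `lfc_cut` and named vector `p_cut`.
#' @export
de_thresholds <- function() {
  list(lfc_cut = 0.6,
       p_cut = c(mRNA = 0.05, lncRNA = 0.05, miRNA = 0.01, circRNA = 0.01))
}

#' Classify features as up, down or not significant
#'
#' A feature is `up` iff `log10_fc >= lfc_cut` and its raw p-value is
#' strictly below its class cutoff; `down` symmetrically; otherwise `ns`.
#' The fold-change boundary is inclusive; the p boundary is strict.
#'
#' @param records Tibble from [nb_wald_test()] (columns `feature_id`,
#'   `rna_class`, `log10_fc`, `p`).
#' @param thresholds As [de_thresholds()].
#' @return `records` with a `status` column added.
#' @export
classify_features <- function(records, thresholds = de_thresholds()) {
  unknown <- setdiff(unique(records$rna_class), names(thresholds$p_cut))
  if (length(unknown)) {
    stop_input(paste0("no p cutoff for class(es): ",
                      paste(unknown, collapse = ", ")))
  }
  cut <- thresholds$p_cut[records$rna_class]
  records |>
    mutate(status = dplyr::case_when(
      is.na(.data$p) ~ "ns",
      .data$log10_fc >= thresholds$lfc_cut & .data$p < cut ~ "up",
      .data$log10_fc <= -thresholds$lfc_cut & .data$p < cut ~ "down",
      TRUE ~ "ns"))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone, capped at 1), with domain
#' validation: all p-values must lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop_input("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Run the full differential-expression stage
#'
#' Size factors, method-of-moments dispersion estimation moderated by the
#' class-median floor (see [moderate_dispersion()]), the NB Wald test, BH
#' adjustment (reported, not used for classification) and class-specific
#' volcano classification in one call.
#'
#' @param es An [expr_set()].
#' @param thresholds As [de_thresholds()].
#' @param pseudocount Passed to [nb_wald_test()].
#' @return A tibble of differential-expression records with `status` and
#'   `p_adj` columns.
#' @export
de_test <- function(es, thresholds = de_thresholds(), pseudocount = 0.5) {
  sf <- size_factors(es)
  alpha <- moderate_dispersion(estimate_dispersion(es, sf),
                               es$features$rna_class)
  rec <- nb_wald_test(es, sf, alpha, pseudocount)
  rec$p_adj <- NA_real_
  ok <- !is.na(rec$p)
  rec$p_adj[ok] <- bh_adjust(rec$p[ok])
  classify_features(rec, thresholds)
}

#' Principal component analysis of samples
#'
#' PCA on `log10(normalized count + 1)`, feature-centered, via SVD. The
#' sign of each component is fixed by making its largest-magnitude feature
#' loading positive, so results are fully deterministic.
#'
#' @param es An [expr_set()] with >= 3 samples.
#' @param size_factors Per-sample factors; computed from `es` if omitted.
#' @return An object of class `cerna_pca`: list with `scores` (tibble:
#'   `sample_id`, `group`, `PC1`, `PC2`, ...) and `variance_explained`
#'   (fractions summing to 1).
#' @export
pca_samples <- function(es, size_factors = NULL) {
  if (ncol(es$counts) < 3) stop_input("PCA needs >= 3 samples")
  sf <- size_factors %||% cernascreen::size_factors(es)
  x <- t(log10(normalized_counts(es, sf) + 1))
  if (all(apply(x, 2, sd) == 0)) stop_input("constant matrix: no variance")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[i, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- bind_cols(tibble(sample_id = es$samples$sample_id,
                             group = es$samples$group),
                      as_tibble(fit$x))
  structure(list(scores = scores, variance_explained = ve),
            class = "cerna_pca")
}

#' @export
print.cerna_pca <- function(x, ...) {
  cat("<cerna_pca>\n")
  cat("  variance explained:",
      paste(sprintf("PC%d=%.1f%%", seq_len(min(4, length(x$variance_explained))),
                    100 * head(x$variance_explained, 4)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname pca_samples
#' @param x A `cerna_pca` object.
#' @param ... Unused.
#' @export
tidy.cerna_pca <- function(x, ...) x$scores

#' @rdname pca_samples
#' @export
glance.cerna_pca <- function(x, ...) {
  tibble(component = seq_along(x$variance_explained),
         variance_explained = x$variance_explained)
}
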