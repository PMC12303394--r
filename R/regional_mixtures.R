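#' Fit a two-component Gaussian mixture to regional SUVR samples
#'
#' Cross-sectional tau PET SUVR in a region is modelled as a mixture of a
#' tau-negative (healthy) and a tau-positive (pathological) Gaussian
#' component. The fit is by EM (via \pkg{mclust}, unequal variances,
#' deterministic model-based initialisation); components are ordered by
#' mean, and AIC scores for the one- and two-component fits are recorded so
#' that regions where a single component suffices can be flagged.
#'
#' @param suvr_samples Numeric vector of at least 20 positive SUVR values.
#' @return Object of class `region_mixture` with fields `weight_neg`,
#'   `weight_pos`, `mean_neg`, `sd_neg`, `mean_pos`, `sd_pos`, `aic_1comp`,
#'   `aic_2comp`, `n`, and the classification-supporting `samples`.
#' @examples
#' x <- c(rnorm(300, 1.1, 0.08), rnorm(120, 1.9, 0.25))
#' fit_region_mixture(x)
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_region_mixture <- function(suvr_samples) {
  x <- as.numeric(suvr_samples)
  if (length(x) < 20) stop("need at least 20 samples, got ", length(x))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("SUVR samples must be positive and finite")
  }
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance")

  fit2 <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  fit1 <- mclust::Mclust(x, G = 1, modelNames = "X", verbose = FALSE)
  if (is.null(fit2) || is.null(fit1)) stop("mixture fit failed to converge")

  ord <- order(fit2$parameters$mean)
  means <- fit2$parameters$mean[ord]
  sds <- sqrt(fit2$parameters$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, 2)  # variance collapsed to equal
  sds <- sds[ord]
  weights <- fit2$parameters$pro[ord]

  structure(
    list(weight_neg = weights[1], weight_pos = weights[2],
         mean_neg = unname(means[1]), sd_neg = unname(sds[1]),
         mean_pos = unname(means[2]), sd_pos = unname(sds[2]),
         aic_1comp = -2 * fit1$loglik + 2 * fit1$df,
         aic_2comp = -2 * fit2$loglik + 2 * fit2$df,
         n = length(x), samples = x),
    class = "region_mixture"
  )
}

#' @export
print.region_mixture <- function(x, ...) {
  cat(sprintf(
    "<region_mixture> T-: %.3f (sd %.3f, w %.2f) | T+: %.3f (sd %.3f, w %.2f)\n",
    x$mean_neg, x$sd_neg, x$weight_neg, x$mean_pos, x$sd_pos, x$weight_pos))
  cat(sprintf("  AIC 1-comp %.1f, 2-comp %.1f%s\n", x$aic_1comp, x$aic_2comp,
              if (x$aic_1comp < x$aic_2comp) " [single component preferred]" else ""))
  invisible(x)
}

#' Derive regional baselines and carrying capacities from fitted mixtures
#'
#' The baseline `s0` of a region is the mean of its tau-negative component;
#' the carrying capacity `sinf` is the 99th percentile of its tau-positive
#' component. By default the percentile is the Gaussian quantile of the
#' fitted positive component (`mean_pos + qnorm(0.99) * sd_pos`), which is
#' reproducible and independent of sample size; `method = "empirical"`
#' instead takes the empirical quantile of the samples assigned to the
#' positive component.
#'
#' @param mixtures Named list of [fit_region_mixture()] results, one per
#'   region.
#' @param prob Upper quantile defining the carrying capacity (default 0.99).
#' @param method `"parametric"` (Gaussian quantile, default) or
#'   `"empirical"`.
#' @return A [regional_params()] in the order of `mixtures`.
#' @export
derive_regional_params <- function(mixtures, prob = 0.99,
                                   method = c("parametric", "empirical")) {
  method <- match.arg(method)
  stopifnot(length(mixtures) > 0)
  s0 <- vapply(mixtures, function(m) m$mean_neg, numeric(1))
  sinf <- vapply(mixtures, function(m) {
    if (method == "parametric") {
      m$mean_pos + stats::qnorm(prob) * m$sd_pos
    } else {
      post <- posterior_positive_probability(m, m$samples)
      pos <- m$samples[post >= 0.5]
      if (length(pos) < 2) stop("too few positive-assigned samples for empirical quantile")
      unname(stats::quantile(pos, prob))
    }
  }, numeric(1))
  bad <- which(sinf <= s0)
  if (length(bad) > 0) {
    stop("carrying capacity does not exceed baseline for region(s): ",
         paste(names(mixtures)[bad], collapse = ", "))
  }
  regional_params(s0, sinf, region_labels = names(mixtures))
}

# Posterior probability that an observation belongs to the positive
# (higher-mean) component, including the mixture weights.
posterior_positive_probability <- function(mixture, x) {
  dn <- mixture$weight_neg * stats::dnorm(x, mixture$mean_neg, mixture$sd_neg)
  dp <- mixture$weight_pos * stats::dnorm(x, mixture$mean_pos, mixture$sd_pos)
  dp / (dn + dp)
}

#' Tau-positivity threshold of a composite region
#'
#' Fits a two-component mixture to per-subject composite SUVR (the mean over
#' the composite's constituent regions) and returns the smallest SUVR at
#' which the posterior probability of belonging to the positive component
#' reaches 50%, located by bisection between the two component means. For an
#' equal-weight, equal-variance mixture this is the midpoint of the means.
#'
#' @param suvr_per_subject_composite Numeric vector of composite SUVR values
#'   (one per subject), or an already fitted [fit_region_mixture()].
#' @param tol Bisection tolerance on the threshold (SUVR units).
#' @return The threshold SUVR (scalar), with the fitted mixture attached as
#'   attribute `"mixture"`.
#' @export
composite_threshold <- function(suvr_per_subject_composite, tol = 1e-9) {
  m <- if (inherits(suvr_per_subject_composite, "region_mixture")) {
    suvr_per_subject_composite
  } else {
    fit_region_mixture(suvr_per_subject_composite)
  }
  f <- function(x) posterior_positive_probability(m, x) - 0.5
  lo <- m$mean_neg
  hi <- m$mean_pos
  if (f(lo) >= 0) return(structure(lo, mixture = m))
  if (f(hi) < 0) {
    stop("posterior positive probability does not reach 50% between the ",
         "component means; mixture components may be indistinct")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  structure((lo + hi) / 2, mixture = m)
}

#' Bundle composite thresholds for tau-positivity classification
#'
#' @param mtl_threshold,neocortical_threshold Positive SUVR thresholds for
#'   the medial temporal and neocortical composites.
#' @param mtl_regions,neocortical_regions Constituent region labels of each
#'   composite.
#' @return Object of class `composite_thresholds`.
#' @export
composite_thresholds <- function(mtl_threshold, neocortical_threshold,
                                 mtl_regions = mtl_composite_regions(),
                                 neocortical_regions = neocortical_composite_regions()) {
  if (mtl_threshold <= 0 || neocortical_threshold <= 0) {
    stop("thresholds must be positive")
  }
  structure(
    list(mtl_threshold = as.numeric(mtl_threshold),
         neocortical_threshold = as.numeric(neocortical_threshold),
         mtl_regions = mtl_regions,
         neocortical_regions = neocortical_regions),
    class = "composite_thresholds"
  )
}

#' Classify a subject as tau-positive or tau-negative
#'
#' A subject is `T+` if, at their last scan, the medial temporal composite
#' strictly exceeds its threshold or the neocortical composite strictly
#' exceeds its threshold; otherwise `T-`. Values exactly at a threshold are
#' negative.
#'
#' @param series A [subject_series()].
#' @param thresholds A [composite_thresholds()].
#' @return `"T+"` or `"T-"`.
#' @export
classify_subject <- function(series, thresholds) {
  stopifnot(inherits(series, "subject_series"),
            inherits(thresholds, "composite_thresholds"))
  labels <- colnames(series$suvr)
  if (is.null(labels)) stop("subject series must have named region columns")
  missing <- setdiff(c(thresholds$mtl_regions, thresholds$neocortical_regions),
                     labels)
  if (length(missing) > 0) {
    stop("composite regions missing from subject series: ",
         paste(missing, collapse = ", "))
  }
  last <- series$suvr[nrow(series$suvr), ]
  mtl <- mean(last[thresholds$mtl_regions])
  neo <- mean(last[thresholds$neocortical_regions])
  if (mtl > thresholds$mtl_threshold || neo > thresholds$neocortical_threshold) {
    "T+"
  } else {
    "T-"
  }
}
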