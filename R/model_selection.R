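#' Free-parameter count of a fitted model family
#'
#' The FKPP forms carry two rates per subject plus four population
#' parameters and the noise scale (`2N + 5`); the single-rate diffusion and
#' logistic models carry one rate per subject plus two population parameters
#' and the noise scale (`N + 3`).
#'
#' @param family Model family name.
#' @param n_subjects Number of subjects `N`.
#' @return Integer parameter count `k`.
#' @examples
#' count_parameters("local_fkpp", 57)  # 119
#' count_parameters("diffusion", 57)   # 60
#' @export
count_parameters <- function(family, n_subjects) {
  n_subjects <- as.integer(n_subjects)
  switch(family,
    local_fkpp = ,
    global_fkpp = 2L * n_subjects + 5L,
    diffusion = ,
    logistic = n_subjects + 3L,
    stop("unknown family: ", family)
  )
}

#' Bayesian information criterion of a fitted hierarchical model
#'
#' `BIC = k * log(n) - 2 * log L`, where `L` is the total data likelihood
#' at the best retained posterior draw (the draw of all sampled parameters
#' jointly maximising the total log-likelihood), `k` the free-parameter
#' count of the family, and `n` the total observation count (scans times
#' regions summed over subjects).
#'
#' @param posterior A [fit_hierarchical()] result (carries the per-draw
#'   total log-likelihood).
#' @param cohort The fitted [cohort()]; defaults to the one stored in the
#'   posterior.
#' @param k,n_obs Optional overrides of the parameter and observation
#'   counts (otherwise derived from the family and cohort).
#' @return Object of class `model_score` with fields `bic`, `k`, `n_obs`,
#'   `max_loglik`, `elpd` (NA until computed), `family`.
#' @export
compute_bic <- function(posterior, cohort = posterior$cohort, k = NULL,
                        n_obs = NULL) {
  stopifnot(inherits(posterior, "hierarchical_posterior"))
  if (length(posterior$loglik) == 0) stop("posterior contains no draws")
  N <- length(posterior$subject_ids)
  if (is.null(k)) k <- count_parameters(posterior$family, N)
  n <- if (is.null(n_obs)) n_observations(cohort) else n_obs
  maxL <- max(posterior$loglik)
  structure(
    list(bic = k * log(n) - 2 * maxL, k = k, n_obs = n, max_loglik = maxL,
         elpd = NA_real_, family = posterior$family),
    class = "model_score"
  )
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("<model_score> %s: BIC %.1f (k = %d, n = %d, max logL %.1f)",
              x$family, x$bic, x$k, x$n_obs, x$max_loglik))
  if (!is.na(x$elpd)) cat(sprintf(", ELPD %.2f", x$elpd))
  cat("\n")
  invisible(x)
}

# numerically stable log(mean(exp(x)))
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Expected log predictive density on held-out scans
#'
#' For each held-out subject, the pointwise predictive density of their
#' unobserved scans is averaged over posterior draws of that subject's rates
#' and the noise scale (log-mean-exp over draws), then summed over subjects.
#' Held-out series must condition on the training initial state (see
#' [holdout_split()]) and every held-out subject must be present in the
#' posterior.
#'
#' @param posterior A [fit_hierarchical()] result.
#' @param held_out_cohort A [cohort()] of held-out series.
#' @param ndraws Number of posterior draws `S` used (evenly thinned;
#'   default all, capped at 1000).
#' @return Scalar ELPD.
#' @export
compute_elpd <- function(posterior, held_out_cohort, ndraws = NULL) {
  stopifnot(inherits(posterior, "hierarchical_posterior"),
            inherits(held_out_cohort, "cohort"))
  ctx <- posterior$context
  missing <- setdiff(names(held_out_cohort$subjects), posterior$subject_ids)
  if (length(missing) > 0) {
    stop("held-out subject(s) absent from the posterior: ",
         paste(missing, collapse = ", "))
  }
  S_all <- nrow(posterior$draws)
  if (is.null(ndraws)) ndraws <- min(S_all, 1000L)
  idx <- unique(round(seq(1, S_all, length.out = min(ndraws, S_all))))
  dr <- posterior$draws[idx, , drop = FALSE]
  S <- nrow(dr)

  subjects <- held_out_cohort$subjects
  N <- length(subjects)
  R <- ctx$n_regions
  grid <- sort(unique(c(0, unlist(lapply(subjects, function(s) s$scan_times)))))
  Y0 <- t(vapply(subjects, function(s) s$initial_state, numeric(R)))
  ids <- names(subjects)

  ll <- matrix(NA_real_, N, S)
  for (s in seq_len(S)) {
    rho <- if (ctx$use_rho) dr[s, paste0("rho[", ids, "]")] else rep(0, N)
    alpha <- if (ctx$use_alpha) dr[s, paste0("alpha[", ids, "]")] else rep(0, N)
    sol <- solve_stacked(ctx, Y0, grid, rho, alpha)
    if (is.null(sol)) { ll[, s] <- -Inf; next }
    for (n in seq_len(N)) {
      cols <- (n - 1) * R + seq_len(R)
      pred <- sol[match(subjects[[n]]$scan_times, grid), cols, drop = FALSE]
      ll[n, s] <- sum(stats::dnorm(subjects[[n]]$suvr, pred, dr[s, "sigma"],
                                   log = TRUE))
    }
  }
  sum(apply(ll, 1, log_mean_exp))
}

#' Per-region residuals of the fitted model at final scans
#'
#' Simulates each subject at their posterior-mean rates and reports the
#' signed error (predicted minus observed) at the final scan, averaged over
#' subjects per region, together with the overall mean and standard
#' deviation across regions.
#'
#' @param posterior A [fit_hierarchical()] result.
#' @param cohort The fitted [cohort()] (defaults to the stored one); every
#'   subject needs at least two scans.
#' @return List with `per_region` (named mean error per region),
#'   `mean_error` and `sd_error` across regions.
#' @export
residual_summary <- function(posterior, cohort = posterior$cohort) {
  stopifnot(inherits(posterior, "hierarchical_posterior"))
  if (any(vapply(cohort$subjects, function(s) s$n_scans, integer(1)) < 2)) {
    stop("every subject needs at least two scans for a final-scan residual")
  }
  ctx <- posterior$context
  ids <- names(cohort$subjects)
  errs <- vapply(ids, function(id) {
    s <- cohort$subjects[[id]]
    rho <- if (ctx$use_rho) mean(posterior$draws[, paste0("rho[", id, "]")]) else 0
    alpha <- if (ctx$use_alpha) mean(posterior$draws[, paste0("alpha[", id, "]")]) else 0
    times <- unique(c(0, s$scan_times))
    sol <- solve_subject(ctx, s$initial_state, times, rho, alpha)
    if (is.null(sol)) stop("ODE solve failed for subject ", id)
    pred_final <- sol[match(max(s$scan_times), times), ]
    pred_final - s$suvr[s$n_scans, ]
  }, numeric(ctx$n_regions))
  per_region <- rowMeans(errs)
  names(per_region) <- ctx$region_labels
  list(per_region = per_region, mean_error = mean(per_region),
       sd_error = stats::sd(per_region))
}

#' Spatially shuffle a cohort and its regional parameters
#'
#' Draws one random permutation of region indices and applies it identically
#' to every subject's SUVR columns (and initial states) and to the regional
#' baselines and carrying capacities, while leaving the connectome
#' untouched. Refitting on shuffled data destroys the correspondence
#' between the data and the network, so transport estimates collapse if (and
#' only if) the original fit exploited genuine network structure.
#'
#' @param cohort A [cohort()].
#' @param regional_params A [regional_params()].
#' @param seed Integer seed for the permutation.
#' @param permutation Optional explicit permutation of `1:R` overriding the
#'   random draw.
#' @return List with `cohort`, `regional_params` and the `permutation` used.
#' @export
spatial_shuffle <- function(cohort, regional_params, seed, permutation = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(regional_params, "regional_params"))
  R <- length(cohort$region_labels)
  if (length(regional_params$baselines) != R) {
    stop("cohort and regional params disagree on the number of regions")
  }
  if (is.null(permutation)) {
    set.seed(seed)
    perm <- sample.int(R)
  } else {
    if (!setequal(permutation, seq_len(R))) stop("invalid permutation")
    perm <- as.integer(permutation)
  }
  labels <- cohort$region_labels
  subjects <- lapply(cohort$subjects, function(s) {
    suvr <- s$suvr[, perm, drop = FALSE]
    colnames(suvr) <- labels  # values move; the label grid stays fixed
    init <- if (abs(s$scan_times[1]) < 1e-12) NULL else s$initial_state[perm]
    subject_series(s$subject_id, s$scan_times, suvr, initial_state = init)
  })
  rp <- regional_params(regional_params$baselines[perm],
                        regional_params$capacities[perm],
                        region_labels = labels)
  list(cohort = cohort(subjects, group_label = cohort$group_label),
       regional_params = rp, permutation = perm)
}

#' Compare two sets of posterior draws with the Mann-Whitney U test
#'
#' Pools the draws of a parameter from one or more posteriors per condition
#' and tests for a location difference, as used to compare true-data and
#' spatially shuffled posteriors.
#'
#' @param draws_a,draws_b Numeric vectors of posterior draws.
#' @return The `htest` result of [stats::wilcox.test()].
#' @export
compare_posteriors_mwu <- function(draws_a, draws_b) {
  stats::wilcox.test(draws_a, draws_b, exact = FALSE)
}
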