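#' Posterior-predictive trajectories for one subject
#'
#' Simulates the fitted model forward from the subject's initial state for
#' each posterior draw (all draws are stacked into a single ODE solve), and
#' optionally adds Gaussian observation noise per draw. If the subject was
#' not part of the fitted cohort, subject-level rates are drawn from the
#' population laws of each posterior draw, with a warning.
#'
#' @param posterior A [fit_hierarchical()] result.
#' @param subject A subject id present in the fit, or a [subject_series()].
#' @param times Forecast times in years from the subject's first scan;
#'   0 is prepended when absent.
#' @param include_noise Add observation noise draws to the trajectories?
#' @param ndraws Number of posterior draws to use (evenly thinned;
#'   default all, capped at 1000).
#' @param seed Seed for noise/population draws (default 1).
#' @return Object of class `posterior_prediction` with the draw array
#'   (`draws x times x regions`) and pointwise 5/50/95% quantile summaries.
#' @export
posterior_predict <- function(posterior, subject, times, include_noise = FALSE,
                              ndraws = NULL, seed = 1L) {
  stopifnot(inherits(posterior, "hierarchical_posterior"))
  ctx <- posterior$context
  if (abs(times[1]) > 1e-12) times <- c(0, times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")

  if (inherits(subject, "subject_series")) {
    id <- subject$subject_id
    y0 <- subject$initial_state
  } else {
    id <- as.character(subject)
    if (!id %in% posterior$subject_ids) {
      stop("subject ", id, " not in the fitted cohort; pass its subject_series")
    }
    y0 <- posterior$cohort$subjects[[id]]$initial_state
  }

  S_all <- nrow(posterior$draws)
  if (is.null(ndraws)) ndraws <- min(S_all, 1000L)
  idx <- unique(round(seq(1, S_all, length.out = min(ndraws, S_all))))
  S <- length(idx)
  dr <- posterior$draws[idx, , drop = FALSE]

  set.seed(seed)
  in_fit <- id %in% posterior$subject_ids
  if (in_fit) {
    rho <- if (ctx$use_rho) dr[, paste0("rho[", id, "]")] else rep(0, S)
    alpha <- if (ctx$use_alpha) dr[, paste0("alpha[", id, "]")] else rep(0, S)
  } else {
    warning("subject ", id, " absent from the posterior; ",
            "drawing rates from the population laws")
    rho <- if (ctx$use_rho) {
      rtruncnorm_pos(S, dr[, "rho_mu"], dr[, "rho_sigma"])
    } else rep(0, S)
    alpha <- if (ctx$use_alpha) {
      stats::rnorm(S, dr[, "alpha_mu"], dr[, "alpha_sigma"])
    } else rep(0, S)
  }

  Y0 <- matrix(y0, nrow = S, ncol = ctx$n_regions, byrow = TRUE)
  sol <- solve_stacked(ctx, Y0, times, rho, alpha)
  if (is.null(sol)) stop("ODE solve failed during posterior prediction")
  arr <- array(NA_real_, c(S, length(times), ctx$n_regions),
               dimnames = list(NULL, signif(times, 8), ctx$region_labels))
  for (s in seq_len(S)) {
    arr[s, , ] <- sol[, (s - 1) * ctx$n_regions + seq_len(ctx$n_regions)]
  }
  if (include_noise) {
    noise <- array(stats::rnorm(length(arr), 0, rep(dr[, "sigma"],
                                                    times = length(times) * ctx$n_regions)),
                   dim = dim(arr))
    noise[, 1, ] <- 0  # the initial state is conditioned on, not predicted
    arr <- arr + noise
  }
  qs <- apply(arr, c(2, 3), stats::quantile, probs = c(0.05, 0.5, 0.95))
  structure(
    list(subject_id = id, times = times, draws = arr,
         quantiles = aperm(qs, c(2, 3, 1)), include_noise = include_noise,
         population_fallback = !in_fit),
    class = "posterior_prediction"
  )
}

#' @export
print.posterior_prediction <- function(x, ...) {
  cat("<posterior_prediction>", x$subject_id, ":", dim(x$draws)[1],
      "draws x", dim(x$draws)[2], "times x", dim(x$draws)[3], "regions",
      if (x$include_noise) "(with observation noise)" else "", "\n")
  invisible(x)
}

#' Iterative forecasting experiment with growing training series
#'
#' Mirrors the scan-accrual forecasting protocol: a fixed training cohort is
#' augmented with the first `k` scans of each test subject, the hierarchical
#' model is refitted, and each test subject's remaining scans beyond the
#' largest `k` are forecast. Reported per iteration: mean absolute held-out
#' error of the posterior-median prediction, empirical coverage of the 90%
#' predictive interval (observation noise included), and the mean interval
#' width.
#'
#' @param train_cohort A [cohort()] used in full at every iteration.
#' @param test_cohort A [cohort()] whose subjects all have more scans than
#'   `max(scans_per_iteration)`, or `NULL` for an empty experiment.
#' @param context A [model_context()].
#' @param scans_per_iteration Increasing training scan counts
#'   (default `c(1, 2, 3)`).
#' @param priors,config Passed to [fit_hierarchical()].
#' @return Data frame with one row per iteration.
#' @export
iterative_forecast_experiment <- function(train_cohort, test_cohort, context,
                                          scans_per_iteration = c(1, 2, 3),
                                          priors = default_priors(),
                                          config = sampler_config()) {
  empty <- data.frame(n_train_scans = integer(0), n_test = integer(0),
                      mean_abs_error = numeric(0), coverage90 = numeric(0),
                      mean_interval_width = numeric(0))
  if (is.null(test_cohort) || length(test_cohort$subjects) == 0) return(empty)
  stopifnot(all(diff(scans_per_iteration) > 0))
  kmax <- max(scans_per_iteration)
  short <- vapply(test_cohort$subjects, function(s) s$n_scans <= kmax, logical(1))
  if (any(short)) {
    stop("test subject(s) with too few scans for ", kmax, "-scan training: ",
         paste(names(short)[short], collapse = ", "))
  }

  rows <- lapply(scans_per_iteration, function(k) {
    truncated <- lapply(test_cohort$subjects, function(s) {
      subject_series(s$subject_id, s$scan_times[seq_len(k)],
                     s$suvr[seq_len(k), , drop = FALSE])
    })
    fit_cohort <- cohort(c(train_cohort$subjects, truncated),
                         group_label = train_cohort$group_label)
    fit <- fit_hierarchical(fit_cohort, context, priors, config)

    err <- cov <- wid <- c()
    for (s in test_cohort$subjects) {
      held <- which(seq_len(s$n_scans) > kmax)
      pp <- posterior_predict(fit, s$subject_id, s$scan_times[held],
                              include_noise = TRUE, seed = config$seed)
      t_idx <- match(s$scan_times[held], pp$times)
      for (j in seq_along(held)) {
        obs <- s$suvr[held[j], ]
        med <- pp$quantiles[t_idx[j], , "50%"]
        lo <- pp$quantiles[t_idx[j], , "5%"]
        hi <- pp$quantiles[t_idx[j], , "95%"]
        err <- c(err, abs(med - obs))
        cov <- c(cov, obs >= lo & obs <= hi)
        wid <- c(wid, hi - lo)
      }
    }
    data.frame(n_train_scans = k, n_test = length(test_cohort$subjects),
               mean_abs_error = mean(err), coverage90 = mean(cov),
               mean_interval_width = mean(wid))
  })
  do.call(rbind, rows)
}
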