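#' Generate a random connected weighted connectome
#'
#' Builds a symmetric, nonnegative, connected weighted graph: a random
#' spanning-tree backbone guarantees connectivity, extra edges are added to
#' reach the requested density, edge weights are log-normal (emulating the
#' heavy-tailed distribution of streamline counts), and regional volumes are
#' drawn uniformly from `volume_range` (on the normalised scale, reference
#' volume 1). With 72 regions the default tau model labels are used.
#'
#' @param n_regions Number of regions (>= 2).
#' @param density Fraction of all possible edges present, in (0, 1].
#' @param weight_scale Median edge weight.
#' @param volume_range Range of normalised regional volumes, within (0, 1].
#' @param seed Integer seed; output is fully determined by the arguments.
#' @return A [connectome()].
#' @examples
#' conn <- generate_connectome(10, density = 0.4, seed = 1)
#' @export
generate_connectome <- function(n_regions = 72, density = 0.3,
                                weight_scale = 1, volume_range = c(0.2, 1),
                                seed = 1L) {
  stopifnot(n_regions >= 2, density > 0, density <= 1,
            volume_range[1] > 0, volume_range[2] <= 1)
  set.seed(seed)
  R <- n_regions
  A <- matrix(0, R, R)
  # spanning-tree backbone: each node attaches to a random earlier node
  order <- sample.int(R)
  for (k in 2:R) {
    i <- order[k]
    j <- order[sample.int(k - 1, 1)]
    A[i, j] <- A[j, i] <- 1
  }
  n_target <- max(R - 1, round(density * R * (R - 1) / 2))
  free <- which(upper.tri(A) & A == 0)
  extra <- n_target - (R - 1)
  if (extra > 0 && length(free) > 0) {
    add <- sample(free, min(extra, length(free)))
    A[add] <- 1
    A <- pmax(A, t(A))
  }
  n_edges <- sum(A[upper.tri(A)] > 0)
  w <- stats::rlnorm(n_edges, meanlog = log(weight_scale), sdlog = 0.75)
  A[upper.tri(A)][A[upper.tri(A)] > 0] <- w
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  volumes <- stats::runif(R, volume_range[1], volume_range[2])
  labels <- if (R == 72) tau_model_regions() else
    sprintf("region_%02d", seq_len(R))
  connectome(A, volumes = volumes, region_labels = labels,
             reference_volume = 1)
}

#' Generate regional baseline/capacity ground truth
#'
#' Baselines are drawn uniformly around the healthy tau SUVR level (about
#' 1.0-1.3 for common tracers) and carrying capacities add a span of 0.4-1.4
#' SUVR, matching the spread of mixture-derived capacities across cortical
#' regions.
#'
#' @param n_regions Number of regions.
#' @param s0_range Range of baselines (SUVR).
#' @param span_range Range of capacity minus baseline (SUVR).
#' @param seed Integer seed.
#' @param region_labels Optional labels (default as in
#'   [generate_connectome()]).
#' @return A [regional_params()].
#' @export
generate_regional_params <- function(n_regions = 72, s0_range = c(1.0, 1.3),
                                     span_range = c(0.4, 1.4), seed = 1L,
                                     region_labels = NULL) {
  set.seed(seed + 211L)
  s0 <- stats::runif(n_regions, s0_range[1], s0_range[2])
  span <- stats::runif(n_regions, span_range[1], span_range[2])
  if (is.null(region_labels)) {
    region_labels <- if (n_regions == 72) tau_model_regions() else
      sprintf("region_%02d", seq_len(n_regions))
  }
  regional_params(s0, s0 + span, region_labels = region_labels)
}

#' Generate cross-sectional SUVR samples for mixture calibration
#'
#' Per region, draws a two-component Gaussian mixture whose negative
#' component is centred on the true baseline `s0_i` and whose positive
#' component is placed so that its Gaussian 99th percentile equals the true
#' carrying capacity `sinf_i`. Feeding the output to
#' [fit_region_mixture()]/[derive_regional_params()] should therefore
#' recover the generating `regional_params`.
#'
#' @param regional_truth A [regional_params()] ground truth.
#' @param n_subjects Samples per region.
#' @param positive_fraction Mixture weight of the pathological component,
#'   in (0, 1).
#' @param sd_neg,sd_pos Component standard deviations (SUVR). The positive
#'   sd is capped per region at `span / (qnorm(0.99) + 2)` so that the
#'   pathological component always sits clearly above the healthy one.
#' @param seed Integer seed.
#' @return `n_subjects x R` matrix of SUVR samples with region columns and
#'   attribute `"positive"` (the true component membership matrix).
#' @export
generate_crosssectional_suvr <- function(regional_truth, n_subjects = 1000,
                                         positive_fraction = 0.3,
                                         sd_neg = 0.08, sd_pos = 0.25,
                                         seed = 1L) {
  stopifnot(inherits(regional_truth, "regional_params"),
            positive_fraction > 0, positive_fraction < 1)
  set.seed(seed + 97L)
  R <- length(regional_truth$baselines)
  z99 <- stats::qnorm(0.99)
  pos <- matrix(stats::runif(n_subjects * R) < positive_fraction, n_subjects, R)
  x <- matrix(NA_real_, n_subjects, R)
  for (i in seq_len(R)) {
    sd_pos_i <- min(sd_pos, regional_truth$qinf[i] / (z99 + 2))
    mu_pos <- regional_truth$capacities[i] - z99 * sd_pos_i
    x[, i] <- ifelse(pos[, i],
                     stats::rnorm(n_subjects, mu_pos, sd_pos_i),
                     stats::rnorm(n_subjects, regional_truth$baselines[i], sd_neg))
  }
  x <- pmax(x, 0.05)  # SUVR is physically positive
  colnames(x) <- if (!is.null(regional_truth$region_labels))
    regional_truth$region_labels else sprintf("region_%02d", seq_len(R))
  attr(x, "positive") <- pos
  x
}

#' Ground-truth settings for synthetic cohort generation
#'
#' Population defaults follow the fitted amyloid-positive/tau-positive
#' population values (transport mean 0.007 and spread 0.011, production mean
#' 0.130 and spread 0.100 per year); the observation noise default of 0.05
#' SUVR is of the order of reported residual spreads.
#'
#' @param connectome A [connectome()].
#' @param regional A [regional_params()] on the same regions.
#' @param rho_mu,rho_sigma Population transport mean and spread.
#' @param alpha_mu,alpha_sigma Population production mean and spread.
#' @param noise_sd Observation noise (SUVR).
#' @param seed Integer seed for subject draws.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(connectome, regional, rho_mu = 0.007,
                         rho_sigma = 0.011, alpha_mu = 0.130,
                         alpha_sigma = 0.100, noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(connectome, "connectome"),
            inherits(regional, "regional_params"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (rho_sigma <= 0 || alpha_sigma <= 0 || rho_mu < 0) {
    stop("population spreads must be positive and rho_mu nonnegative")
  }
  structure(
    list(connectome = connectome, regional = regional,
         population = c(rho_mu = unname(rho_mu), rho_sigma = unname(rho_sigma),
                        alpha_mu = unname(alpha_mu),
                        alpha_sigma = unname(alpha_sigma)),
         noise_sd = unname(noise_sd), seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Generate a longitudinal synthetic cohort from known ground truth
#'
#' Subject rates are drawn from the population laws (transport truncated to
#' nonnegative values). Disease initiation seeds the configured regions at
#' the midpoint `(s0 + sinf) / 2` with all other regions at baseline; each
#' subject is then observed after a disease duration drawn uniformly from
#' `onset_years`, by evolving the seeded state forward under that subject's
#' own rates. The default duration range emulates an established-pathology
#' (tau-positive) cohort in which signal has already spread beyond the seed
#' regions; use `onset_years = c(0, 0)` for a seed-only early-disease
#' cohort. From the observed initial state, scans follow the requested
#' family with gaps drawn uniformly from `scan_interval_years`, and i.i.d.
#' Gaussian observation noise is added to every follow-up scan. The first
#' scan is the (noise-free) initial state, which is exactly the
#' conditioning assumption of the hierarchical model.
#'
#' @param truth A [ground_truth()].
#' @param n_subjects Number of subjects.
#' @param scans_per_subject Scans per subject (>= 1).
#' @param scan_interval_years Length-2 range of between-scan gaps (years).
#' @param family Generating model family.
#' @param seed_regions Labels of regions seeded above baseline (default:
#'   regions whose label contains "entorhinal"; falls back to the first two
#'   regions).
#' @param onset_years Length-2 range of per-subject disease duration before
#'   the first scan (years).
#' @param seed Integer seed.
#' @return List with `cohort` (a [cohort()]) and `truth` (the input truth
#'   plus the realised `subject_params` data frame).
#' @export
generate_cohort <- function(truth, n_subjects = 20, scans_per_subject = 3,
                            scan_interval_years = c(1, 2),
                            family = "local_fkpp", seed_regions = NULL,
                            onset_years = c(10, 25), seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), scans_per_subject >= 1)
  set.seed(seed + 389L)
  conn <- truth$connectome
  lap <- volume_weight(build_laplacian(conn), conn)
  ctx <- model_context(lap, truth$regional, family, rtol = 1e-8, atol = 1e-10)
  pop <- truth$population
  R <- ctx$n_regions

  rho_n <- if (ctx$use_rho) {
    rtruncnorm_pos(n_subjects, pop["rho_mu"], pop["rho_sigma"])
  } else rep(0, n_subjects)
  alpha_n <- if (ctx$use_alpha) {
    stats::rnorm(n_subjects, pop["alpha_mu"], pop["alpha_sigma"])
  } else rep(0, n_subjects)

  if (is.null(seed_regions)) {
    seed_regions <- grep("entorhinal", conn$region_labels, value = TRUE)
    if (length(seed_regions) == 0) seed_regions <- conn$region_labels[1:2]
  }
  seed_idx <- match(seed_regions, conn$region_labels)
  if (any(is.na(seed_idx))) {
    stop("seed region(s) not in connectome: ",
         paste(seed_regions[is.na(seed_idx)], collapse = ", "))
  }
  y_seed <- truth$regional$baselines
  y_seed[seed_idx] <- (truth$regional$baselines[seed_idx] +
                         truth$regional$capacities[seed_idx]) / 2
  onset_n <- stats::runif(n_subjects, onset_years[1], onset_years[2])

  subjects <- vector("list", n_subjects)
  for (n in seq_len(n_subjects)) {
    y0 <- if (onset_n[n] > 0) {
      pre <- solve_subject(ctx, y_seed, c(0, onset_n[n]), rho_n[n], alpha_n[n],
                           rtol = 1e-8, atol = 1e-10)
      if (is.null(pre)) stop("pre-scan disease trajectory failed to integrate")
      pre[2, ]
    } else {
      y_seed
    }
    gaps <- stats::runif(max(scans_per_subject - 1, 0),
                         scan_interval_years[1], scan_interval_years[2])
    times <- c(0, cumsum(gaps))
    if (scans_per_subject == 1) {
      suvr <- matrix(y0, 1, R)
    } else {
      sol <- solve_subject(ctx, y0, times, rho_n[n], alpha_n[n],
                           rtol = 1e-8, atol = 1e-10)
      if (is.null(sol)) stop("ground-truth trajectory failed to integrate")
      noise <- matrix(stats::rnorm(length(sol), 0, truth$noise_sd),
                      nrow(sol), ncol(sol))
      noise[1, ] <- 0  # first scan defines the initial condition
      suvr <- sol + noise
    }
    suvr <- pmax(suvr, 0.05)
    colnames(suvr) <- conn$region_labels
    subjects[[n]] <- subject_series(sprintf("sub_%03d", n), times, suvr)
  }

  truth$subject_params <- data.frame(
    subject_id = sprintf("sub_%03d", seq_len(n_subjects)),
    rho = rho_n, alpha = alpha_n, onset_years = onset_n)
  truth$family <- family
  truth$seed_regions <- seed_regions
  list(cohort = cohort(subjects, group_label = "custom"), truth = truth)
}
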