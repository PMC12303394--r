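#' Regional baseline and carrying-capacity parameters
#'
#' Holds the per-region healthy baseline SUVR `s0` and late-disease carrying
#' capacity `sinf` that give each region its own production dynamics. The
#' difference `qinf = sinf - s0` sets the regional production span; regions
#' with larger spans accumulate signal faster under the same global
#' production rate, which is how the model expresses regional vulnerability.
#'
#' @param baselines Numeric vector `s0` of healthy baseline SUVR per region.
#' @param capacities Numeric vector `sinf` of carrying capacities; must be
#'   strictly greater than `baselines` element-wise.
#' @param region_labels Optional character vector of region labels.
#' @return Object of class `regional_params` with fields `baselines`,
#'   `capacities`, `qinf`, `region_labels`.
#' @export
regional_params <- function(baselines, capacities, region_labels = NULL) {
  baselines <- as.numeric(baselines)
  capacities <- as.numeric(capacities)
  if (length(baselines) != length(capacities)) {
    stop("baselines and capacities must have equal length")
  }
  if (any(!is.finite(baselines)) || any(!is.finite(capacities)) ||
      any(baselines <= 0) || any(capacities <= 0)) {
    stop("baselines and capacities must be finite and positive")
  }
  bad <- which(capacities <= baselines)
  if (length(bad) > 0) {
    lab <- if (is.null(region_labels)) bad else region_labels[bad]
    stop("carrying capacity must exceed baseline in every region; violated at: ",
         paste(lab, collapse = ", "))
  }
  if (!is.null(region_labels)) {
    if (length(region_labels) != length(baselines)) {
      stop("region_labels length mismatch")
    }
    names(baselines) <- names(capacities) <- region_labels
  }
  structure(
    list(baselines = baselines, capacities = capacities,
         qinf = capacities - baselines, region_labels = region_labels),
    class = "regional_params"
  )
}

#' @export
print.regional_params <- function(x, ...) {
  cat("<regional_params>", length(x$baselines), "regions; s0 in [",
      signif(min(x$baselines), 3), ",", signif(max(x$baselines), 3),
      "], sinf in [", signif(min(x$capacities), 3), ",",
      signif(max(x$capacities), 3), "]\n")
  invisible(x)
}

#' Specify a member of the network reaction-diffusion model family
#'
#' Five families are available:
#' \describe{
#'   \item{`local_fkpp`}{transport plus regionally varying logistic
#'     production between `s0` and `sinf` (the full model).}
#'   \item{`global_fkpp`}{same form with scalar bounds `min(s0)` and
#'     `max(sinf)` shared by all regions.}
#'   \item{`diffusion`}{transport only (`alpha = 0`); conserves the
#'     volume-weighted total signal.}
#'   \item{`logistic`}{production only (`rho = 0`); regions evolve
#'     independently.}
#'   \item{`heterodimer`}{coupled healthy/toxic protein kinetics, whose
#'     linearised toxic dynamics reduce to the FKPP form.}
#' }
#'
#' @param family Model family name.
#' @param transport_rate Nonnegative transport rate `rho` (per year).
#' @param production_rate Production rate `alpha` (per year per SUVR for the
#'   FKPP forms); may be negative, representing net clearance/atrophy.
#' @param heterodimer_rates For `family = "heterodimer"` only: a list with
#'   positive elements `k0` (healthy production), `k1` (healthy clearance),
#'   `k12` (conversion), and `k1t` (toxic clearance; scalar or per-region
#'   vector).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("local_fkpp", "global_fkpp", "diffusion",
                                  "logistic", "heterodimer"),
                       transport_rate = 0, production_rate = 0,
                       heterodimer_rates = NULL) {
  family <- match.arg(family)
  if (!is.finite(transport_rate) || transport_rate < 0) {
    stop("transport_rate must be a nonnegative scalar")
  }
  if (!is.finite(production_rate)) stop("production_rate must be finite")
  if (family == "heterodimer") {
    r <- heterodimer_rates
    if (is.null(r) || !all(c("k0", "k1", "k12", "k1t") %in% names(r))) {
      stop("heterodimer family requires heterodimer_rates = list(k0, k1, k12, k1t)")
    }
    if (any(unlist(r) <= 0)) stop("heterodimer rates must be positive")
  } else if (!is.null(heterodimer_rates)) {
    stop("heterodimer_rates only apply to the heterodimer family")
  }
  structure(
    list(family = family, transport_rate = transport_rate,
         production_rate = production_rate,
         heterodimer_rates = heterodimer_rates),
    class = "model_spec"
  )
}

#' Right-hand side of the local FKPP model
#'
#' Computes `ds/dt = -rho * Lw %*% (s - s0) + alpha * (s - s0) *
#' ((sinf - s0) - (s - s0))` for a state vector of regional SUVR. This is
#' the reference (pure R) implementation; [simulate_model()] integrates a
#' compiled equivalent.
#'
#' @param state Numeric vector of regional SUVR.
#' @param laplacian A [build_laplacian()]/[volume_weight()] result.
#' @param params A [regional_params()].
#' @param rho Transport rate.
#' @param alpha Production rate.
#' @return Numeric vector of time derivatives.
#' @export
rhs_local_fkpp <- function(state, laplacian, params, rho, alpha) {
  R <- nrow(laplacian$matrix)
  if (length(state) != R || length(params$baselines) != R) {
    stop("dimension mismatch: state has ", length(state), " regions, laplacian ",
         R, ", params ", length(params$baselines))
  }
  d <- state - params$baselines
  as.numeric(-rho * (laplacian$matrix %*% d) + alpha * d * (params$qinf - d))
}

#' Right-hand side of the heterodimer model
#'
#' Coupled kinetics of healthy (`p`) and toxic (`ptilde`) protein: healthy
#' protein is produced at rate `k0`, cleared at `k1`, and converted to toxic
#' protein at rate `k12 * p * ptilde`; toxic protein is cleared at `k1t`
#' (optionally region-specific) and both species are transported along the
#' network.
#'
#' @param healthy,toxic Numeric vectors of length R.
#' @param laplacian A `laplacian` object.
#' @param rates List with positive `k0`, `k1`, `k12`, `k1t`.
#' @param rho Transport rate.
#' @return List with components `healthy` and `toxic` of derivatives.
#' @export
rhs_heterodimer <- function(healthy, toxic, laplacian, rates, rho = 0) {
  R <- nrow(laplacian$matrix)
  if (length(healthy) != R || length(toxic) != R) {
    stop("dimension mismatch: expected ", R, " regions")
  }
  if (any(unlist(rates[c("k0", "k1", "k12")]) <= 0) || any(rates$k1t <= 0)) {
    stop("heterodimer rates must be positive")
  }
  k1t <- rep(rates$k1t, length.out = R)
  conv <- rates$k12 * healthy * toxic
  list(
    healthy = as.numeric(-rho * (laplacian$matrix %*% healthy) +
                           rates$k0 - rates$k1 * healthy - conv),
    toxic = as.numeric(-rho * (laplacian$matrix %*% toxic) -
                         k1t * toxic + conv)
  )
}

#' A simulated (or observed) multi-region time course
#'
#' @param times Strictly increasing numeric vector (years).
#' @param values `length(times) x R` numeric matrix, one column per region.
#' @param scale Either `"suvr"` (raw tracer scale) or `"concentration"`
#'   (rescaled to the unit interval between baseline and capacity).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(times, values, scale = c("suvr", "concentration")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (length(times) != nrow(values)) stop("times and values rows must match")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("trajectory values must be finite")
  structure(list(times = as.numeric(times), values = values, scale = scale),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", nrow(x$values), "time points x", ncol(x$values),
      "regions on", x$scale, "scale, t in [", min(x$times), ",",
      max(x$times), "] years\n")
  invisible(x)
}

# Map a model spec + regional params to the effective (s0, qinf, rho, alpha)
# used by the shared FKPP right-hand side. Global FKPP collapses the regional
# parameters to scalar bounds min(s0) / max(sinf); diffusion and logistic
# zero out production and transport respectively.
effective_fkpp_params <- function(spec, params, n_regions) {
  s0 <- params$baselines
  qinf <- params$qinf
  rho <- spec$transport_rate
  alpha <- spec$production_rate
  switch(spec$family,
    local_fkpp = {},
    logistic = rho <- 0,
    diffusion = alpha <- 0,
    global_fkpp = {
      s0 <- rep(min(params$baselines), n_regions)
      qinf <- rep(max(params$capacities) - min(params$baselines), n_regions)
    },
    stop("unsupported family: ", spec$family)
  )
  list(s0 = as.numeric(s0), qinf = as.numeric(qinf), rho = rho, alpha = alpha)
}

#' Integrate a model of the reaction-diffusion family
#'
#' Numerically integrates the requested model family from an initial state
#' with an adaptive, stiff-capable solver (`deSolve::lsoda` driving compiled
#' right-hand sides). For the heterodimer family the initial state must
#' stack healthy then toxic concentrations (length `2R`) and the returned
#' trajectory is on the concentration scale with columns
#' `healthy_*`/`toxic_*`.
#'
#' @param spec A [model_spec()].
#' @param laplacian A `laplacian` object (volume-weighted or not).
#' @param params A [regional_params()]; ignored by the heterodimer family.
#' @param initial_state Numeric initial state (length R, or 2R for the
#'   heterodimer).
#' @param times Strictly increasing output times in years; the first entry
#'   is the initial time.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @return A [trajectory()].
#' @examples
#' conn <- connectome(matrix(c(0, 1, 1, 0), 2))
#' lap <- build_laplacian(conn)
#' par <- regional_params(c(1.1, 1.2), c(2.0, 2.6))
#' spec <- model_spec("local_fkpp", transport_rate = 0.02, production_rate = 0.2)
#' simulate_model(spec, lap, par, c(1.6, 1.2), times = 0:5)
#' @export
simulate_model <- function(spec, laplacian, params, initial_state, times,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "model_spec"), inherits(laplacian, "laplacian"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(initial_state))) stop("initial_state must be finite")
  R <- nrow(laplacian$matrix)

  if (spec$family == "heterodimer") {
    if (length(initial_state) != 2 * R) {
      stop("heterodimer initial_state must have length 2R = ", 2 * R)
    }
    r <- spec$heterodimer_rates
    parms <- c(R, spec$transport_rate, r$k0, r$k1, r$k12,
               rep(r$k1t, length.out = R), as.vector(laplacian$matrix))
    out <- deSolve::ode(y = as.numeric(initial_state), times = times,
                        func = "tauspread_heterodimer", parms = parms,
                        dllname = "tauspread", initfunc = "tauspread_initmod",
                        rtol = rtol, atol = atol)
    check_ode_output(out, times)
    vals <- unname(out[, -1, drop = FALSE])
    lab <- laplacian$region_labels
    colnames(vals) <- c(paste0("healthy_", lab), paste0("toxic_", lab))
    return(trajectory(times, vals, scale = "concentration"))
  }

  stopifnot(inherits(params, "regional_params"))
  if (length(initial_state) != R || length(params$baselines) != R) {
    stop("dimension mismatch between initial_state, laplacian and params")
  }
  eff <- effective_fkpp_params(spec, params, R)
  parms <- c(R, eff$rho, eff$alpha, eff$s0, eff$qinf,
             as.vector(laplacian$matrix))
  out <- deSolve::ode(y = as.numeric(initial_state), times = times,
                      func = "tauspread_fkpp", parms = parms,
                      dllname = "tauspread", initfunc = "tauspread_initmod",
                      rtol = rtol, atol = atol)
  check_ode_output(out, times)
  vals <- unname(out[, -1, drop = FALSE])
  colnames(vals) <- laplacian$region_labels
  trajectory(times, vals, scale = "suvr")
}

check_ode_output <- function(out, times) {
  if (nrow(out) < length(times) || any(!is.finite(out))) {
    diag <- attr(out, "istate")
    stop("ODE integration failed (returned ", nrow(out), "/", length(times),
         " time points; istate = ",
         if (is.null(diag)) "unknown" else diag[1], ")")
  }
  invisible(out)
}

#' Rescale an SUVR trajectory to regional concentration
#'
#' Applies the change of variables `q_i = (s_i - s0_i) / (sinf_i - s0_i)`,
#' under which the local FKPP model becomes a standard network FKPP equation
#' and regional signal evolves between 0 (healthy) and 1 (carrying
#' capacity).
#'
#' @param traj A [trajectory()] on the SUVR scale.
#' @param params A [regional_params()] matching the trajectory's regions.
#' @return A [trajectory()] on the concentration scale.
#' @export
rescale_to_concentration <- function(traj, params) {
  stopifnot(inherits(traj, "trajectory"), inherits(params, "regional_params"))
  if (traj$scale != "suvr") stop("trajectory is already on the concentration scale")
  if (ncol(traj$values) != length(params$baselines)) {
    stop("trajectory and params disagree on the number of regions")
  }
  if (any(params$qinf == 0)) stop("zero capacity span: cannot rescale")
  q <- sweep(sweep(traj$values, 2, params$baselines, `-`), 2, params$qinf, `/`)
  trajectory(traj$times, q, scale = "concentration")
}

#' Average a concentration trajectory over Braak stages
#'
#' Computes, at every time point, the unweighted mean concentration over the
#' regions assigned to each Braak stage. Used to check that seeded
#' simulations reproduce the stereotyped staging order (entorhinal stage
#' invaded first, primary sensory cortex last).
#'
#' @param traj A [trajectory()] on the concentration scale with named
#'   region columns.
#' @param braak_assignment Named vector mapping every region of the
#'   trajectory to a stage (e.g. [dk_braak_stages()]).
#' @return A `stages x times` matrix of stage-mean concentrations.
#' @export
braak_region_means <- function(traj, braak_assignment = dk_braak_stages(colnames(traj$values))) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$scale != "concentration") {
    stop("braak_region_means expects a concentration-scale trajectory; ",
         "use rescale_to_concentration() first")
  }
  regions <- colnames(traj$values)
  if (is.null(regions)) stop("trajectory must have named region columns")
  missing <- setdiff(regions, names(braak_assignment))
  if (length(missing) > 0) {
    stop("regions missing from braak assignment: ", paste(missing, collapse = ", "))
  }
  stage <- braak_assignment[regions]
  stages <- sort(unique(stage))
  out <- t(vapply(stages, function(st) {
    rowMeans(traj$values[, stage == st, drop = FALSE])
  }, numeric(length(traj$times))))
  rownames(out) <- paste0("stage_", stages)
  colnames(out) <- signif(traj$times, 6)
  out
}
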