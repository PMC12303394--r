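#' Read a connectome from adjacency and volume CSV files
#'
#' The adjacency file must be a square numeric matrix with region labels as
#' both header row and first column; the volumes file maps `region,volume`.
#' The label sets must match exactly (ordering follows the adjacency file).
#'
#' @param path_adjacency Path to the adjacency CSV.
#' @param path_volumes Optional path to the volumes CSV; without it all
#'   volumes are 1.
#' @param ... Passed to [connectome()] (e.g. `asym_tol`).
#' @return A [connectome()].
#' @export
read_connectome_csv <- function(path_adjacency, path_volumes = NULL, ...) {
  adj <- utils::read.csv(path_adjacency, row.names = 1, check.names = FALSE)
  A <- as.matrix(adj)
  if (!is.numeric(A)) {
    bad <- which(!vapply(adj, is.numeric, logical(1)))
    stop("non-numeric adjacency column(s): ",
         paste(colnames(adj)[bad], collapse = ", "))
  }
  if (!identical(rownames(A), colnames(A))) {
    stop("adjacency row and column labels differ")
  }
  volumes <- NULL
  if (!is.null(path_volumes)) {
    vt <- utils::read.csv(path_volumes, check.names = FALSE)
    if (ncol(vt) < 2) stop("volumes CSV needs columns: region, volume")
    volumes <- stats::setNames(as.numeric(vt[[2]]), as.character(vt[[1]]))
    missing <- setdiff(rownames(A), names(volumes))
    if (length(missing) > 0) {
      stop("volumes file missing region(s): ", paste(missing, collapse = ", "))
    }
    extra <- setdiff(names(volumes), rownames(A))
    if (length(extra) > 0) {
      stop("volumes file has unknown region(s): ", paste(extra, collapse = ", "))
    }
  }
  connectome(A, volumes = volumes, region_labels = rownames(A), ...)
}

#' Write a connectome to CSV files
#'
#' @param conn A [connectome()].
#' @param path_adjacency Output path for the adjacency CSV.
#' @param path_volumes Optional output path for the volumes CSV.
#' @return Invisibly, `conn`.
#' @export
write_connectome_csv <- function(conn, path_adjacency, path_volumes = NULL) {
  stopifnot(inherits(conn, "connectome"))
  utils::write.csv(as.data.frame(conn$adjacency), path_adjacency)
  if (!is.null(path_volumes)) {
    utils::write.csv(data.frame(region = conn$region_labels,
                                volume = unname(conn$volumes)),
                     path_volumes, row.names = FALSE)
  }
  invisible(conn)
}

#' Read a longitudinal SUVR table in long format
#'
#' Expects columns `subject_id`, `scan_time_years`, `region`, `suvr` (one
#' row per subject/scan/region) and pivots them into a [cohort()]. Scan
#' times are re-zeroed to each subject's first scan; non-monotone scan rows
#' are sorted with a warning; duplicated (scan, region) pairs and scans with
#' missing regions are errors.
#'
#' @param path CSV path.
#' @param min_scans When set, drop subjects with fewer scans (count
#'   reported via message), e.g. 3 to restrict to series long enough for
#'   time-series modelling.
#' @param drop_zero_change Drop subjects having at least two scans with
#'   zero change from their first scan in every region (flat duplicated
#'   uploads).
#' @param group_label Cohort label.
#' @return A [cohort()].
#' @export
read_suvr_long <- function(path, min_scans = NULL, drop_zero_change = FALSE,
                           group_label = "custom") {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("subject_id", "scan_time_years", "region", "suvr")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("SUVR table missing column(s): ", paste(missing, collapse = ", "))
  }
  regions <- unique(as.character(df$region))
  subjects <- list()
  for (id in unique(as.character(df$subject_id))) {
    d <- df[df$subject_id == id, ]
    times <- sort(unique(d$scan_time_years))
    if (!identical(order(unique(d$scan_time_years)),
                   seq_along(unique(d$scan_time_years)))) {
      warning("scan times out of order for subject ", id, "; sorted")
    }
    if (anyDuplicated(d[, c("scan_time_years", "region")])) {
      stop("duplicated (scan, region) rows for subject ", id)
    }
    mat <- matrix(NA_real_, length(times), length(regions),
                  dimnames = list(NULL, regions))
    mat[cbind(match(d$scan_time_years, times),
              match(as.character(d$region), regions))] <- d$suvr
    if (any(is.na(mat))) {
      j <- which(is.na(mat), arr.ind = TRUE)[1, ]
      stop("subject ", id, " scan at t=", times[j[1]],
           " missing region ", regions[j[2]])
    }
    subjects[[length(subjects) + 1]] <-
      subject_series(id, times - times[1], mat)
  }
  if (!is.null(min_scans)) {
    short <- vapply(subjects, function(s) s$n_scans < min_scans, logical(1))
    if (any(short)) {
      message("dropping ", sum(short), " subject(s) with fewer than ",
              min_scans, " scans")
      subjects <- subjects[!short]
    }
  }
  if (drop_zero_change) {
    flat <- vapply(subjects, function(s) {
      if (s$n_scans < 2) return(FALSE)
      base <- s$suvr[1, ]
      sum(apply(s$suvr, 1, function(row) all(row == base))) >= 2
    }, logical(1))
    if (any(flat)) {
      message("dropping ", sum(flat),
              " subject(s) with duplicated zero-change scans")
      subjects <- subjects[!flat]
    }
  }
  if (length(subjects) == 0) stop("no subjects left after filtering")
  cohort(subjects, group_label = group_label)
}

#' Write a cohort as a long-format SUVR table
#'
#' @param cohort A [cohort()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_suvr_long <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    data.frame(
      subject_id = s$subject_id,
      scan_time_years = rep(s$scan_times, each = ncol(s$suvr)),
      region = rep(colnames(s$suvr), times = length(s$scan_times)),
      suvr = as.vector(t(s$suvr)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Persist posterior draws and diagnostics to disk
#'
#' Draws go to a CSV (one row per retained draw, with chain index and total
#' log-likelihood); diagnostics, priors and configuration go to a JSON
#' sidecar.
#'
#' @param posterior A [fit_hierarchical()] result.
#' @param dir Output directory (created if needed).
#' @param stem File stem (default `"posterior"`).
#' @return Invisibly, the paths written.
#' @export
save_posterior_csv <- function(posterior, dir, stem = "posterior") {
  stopifnot(inherits(posterior, "hierarchical_posterior"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  draws_path <- file.path(dir, paste0(stem, "_draws.csv"))
  meta_path <- file.path(dir, paste0(stem, "_meta.json"))
  df <- data.frame(chain = posterior$chain, loglik = posterior$loglik,
                   posterior$draws, check.names = FALSE)
  utils::write.csv(df, draws_path, row.names = FALSE)
  jsonlite::write_json(
    list(family = posterior$family,
         subject_ids = posterior$subject_ids,
         config = posterior$config,
         priors = posterior$priors,
         diagnostics = list(
           rhat = as.list(posterior$diagnostics$rhat),
           accept_rates = as.list(posterior$diagnostics$accept_rates),
           ode_failures = posterior$diagnostics$ode_failures)),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(draws = draws_path, meta = meta_path))
}
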