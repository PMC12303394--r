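#' Longitudinal regional SUVR series of one subject
#'
#' Scan times are measured in years from the subject's first scan, so
#' `scan_times[1]` must be 0 unless an explicit `initial_state` is given
#' (used for held-out series whose conditioning initial state is an earlier
#' training scan). The initial state defaults to the first scan row.
#'
#' @param subject_id Identifier (coerced to character).
#' @param scan_times Strictly increasing numeric vector of scan times
#'   (years).
#' @param suvr `length(scan_times) x R` matrix of regional SUVR with region
#'   labels as column names.
#' @param initial_state Optional length-R vector: the state at time 0 from
#'   which model trajectories for this subject start.
#' @return Object of class `subject_series`.
#' @export
subject_series <- function(subject_id, scan_times, suvr, initial_state = NULL) {
  suvr <- as.matrix(suvr)
  scan_times <- as.numeric(scan_times)
  if (length(scan_times) < 1) stop("subject needs at least one scan")
  if (nrow(suvr) != length(scan_times)) {
    stop("suvr must have one row per scan")
  }
  if (any(diff(scan_times) <= 0)) stop("scan_times must be strictly increasing")
  if (any(!is.finite(suvr)) || any(suvr <= 0)) {
    stop("SUVR values must be finite and positive")
  }
  if (is.null(initial_state)) {
    if (abs(scan_times[1]) > 1e-12) {
      stop("scan_times must start at 0 (years since first scan); got ",
           scan_times[1])
    }
    initial_state <- suvr[1, ]
  } else {
    if (length(initial_state) != ncol(suvr)) {
      stop("initial_state length must match the number of regions")
    }
    if (scan_times[1] <= 0) {
      stop("with an explicit initial_state, scan_times must be positive ",
           "(time since the conditioning state)")
    }
  }
  structure(
    list(subject_id = as.character(subject_id), scan_times = scan_times,
         suvr = suvr, initial_state = as.numeric(initial_state),
         n_scans = length(scan_times)),
    class = "subject_series"
  )
}

#' @export
print.subject_series <- function(x, ...) {
  cat("<subject_series>", x$subject_id, ":", x$n_scans, "scans x",
      ncol(x$suvr), "regions over", signif(max(x$scan_times), 4), "years\n")
  invisible(x)
}

#' A cohort of subjects sharing a region ordering
#'
#' @param subjects List of [subject_series()] objects.
#' @param group_label Cohort label, e.g. one of the amyloid/tau biomarker
#'   groups `"A+T+"`, `"A+T-"`, `"A-T-"`, or `"custom"`.
#' @return Object of class `cohort`.
#' @export
cohort <- function(subjects, group_label = "custom") {
  if (length(subjects) < 1) stop("cohort needs at least one subject")
  if (!all(vapply(subjects, inherits, logical(1), "subject_series"))) {
    stop("all elements must be subject_series objects")
  }
  labels <- colnames(subjects[[1]]$suvr)
  for (s in subjects[-1]) {
    if (!identical(colnames(s$suvr), labels)) {
      stop("all subjects must share the same region ordering (checked by label)")
    }
  }
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(subjects) <- ids
  structure(
    list(subjects = subjects, group_label = group_label,
         region_labels = labels, n_subjects = length(subjects)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  scans <- vapply(x$subjects, function(s) s$n_scans, integer(1))
  cat("<cohort>", x$group_label, ":", x$n_subjects, "subjects,",
      sum(scans), "scans,", length(x$region_labels), "regions\n")
  invisible(x)
}

#' Total observation count of a cohort
#'
#' Counts scans times regions summed over subjects, the `n` entering the
#' BIC penalty.
#'
#' @param cohort A [cohort()].
#' @return Integer count.
#' @export
n_observations <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  R <- length(cohort$region_labels)
  sum(vapply(cohort$subjects, function(s) s$n_scans, integer(1))) * R
}

#' Split every subject's scans into training and held-out series
#'
#' The first `n_train_scans` scans of each subject form the training series;
#' the remaining scans form a held-out series whose conditioning initial
#' state is the training series' first scan (so held-out scan times stay on
#' the training clock). Subjects without scans beyond `n_train_scans`
#' contribute only to the training cohort.
#'
#' @param cohort A [cohort()].
#' @param n_train_scans Number of leading scans per subject to train on.
#' @return List with `train` (a cohort) and `test` (a cohort of held-out
#'   series, or `NULL` when no subject has extra scans).
#' @export
holdout_split <- function(cohort, n_train_scans) {
  stopifnot(inherits(cohort, "cohort"), n_train_scans >= 1)
  train <- list()
  test <- list()
  for (s in cohort$subjects) {
    k <- min(n_train_scans, s$n_scans)
    train[[length(train) + 1]] <- subject_series(
      s$subject_id, s$scan_times[seq_len(k)], s$suvr[seq_len(k), , drop = FALSE])
    if (s$n_scans > n_train_scans) {
      idx <- seq(n_train_scans + 1, s$n_scans)
      test[[length(test) + 1]] <- subject_series(
        s$subject_id, s$scan_times[idx], s$suvr[idx, , drop = FALSE],
        initial_state = s$suvr[1, ])
    }
  }
  list(
    train = cohort(train, group_label = cohort$group_label),
    test = if (length(test) > 0) cohort(test, group_label = cohort$group_label)
  )
}
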