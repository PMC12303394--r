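#' Construct and validate a structural connectome
#'
#' A connectome bundles the streamline-count adjacency matrix `A` of a
#' region-parcellated tractography analysis with per-region volumes and a
#' reference volume. All dynamics in the package run on graph Laplacians
#' derived from this object.
#'
#' The adjacency must be square, nonnegative and (up to small numerical
#' error) symmetric with a zero diagonal. Matrices that are asymmetric within
#' a relative tolerance of `asym_tol` are symmetrised as `(A + t(A)) / 2`
#' with a warning; larger asymmetries are treated as data faults and raise an
#' error naming the worst entries.
#'
#' @param adjacency Square numeric matrix of streamline counts (or weights).
#' @param volumes Positive numeric vector of regional volumes, one per
#'   region. Defaults to 1 for every region (no volume weighting).
#' @param region_labels Character vector of unique region identifiers.
#'   Defaults to `rownames(adjacency)`, or `region_1 ... region_R`.
#' @param reference_volume Positive scalar reference volume `vr`. Defaults to
#'   `max(volumes)`, so that normalised volumes lie in (0, 1].
#' @param asym_tol Relative tolerance below which asymmetry is repaired by
#'   symmetrisation rather than raised as an error.
#' @return An object of class `connectome` with fields `adjacency`,
#'   `volumes`, `region_labels`, `reference_volume`.
#' @examples
#' conn <- connectome(matrix(c(0, 2, 2, 0), 2), volumes = c(1, 2))
#' conn$region_labels
#' @export
connectome <- function(adjacency, volumes = NULL, region_labels = NULL,
                       reference_volume = NULL, asym_tol = 1e-8) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square, got ", nrow(adjacency), "x", ncol(adjacency))
  }
  R <- nrow(adjacency)
  if (R < 1) stop("adjacency must have at least one region")
  if (!is.numeric(adjacency) || any(!is.finite(adjacency))) {
    stop("adjacency must be finite numeric")
  }
  if (any(adjacency < 0)) {
    bad <- which(adjacency < 0, arr.ind = TRUE)
    stop("adjacency has negative entries, e.g. at (",
         bad[1, 1], ",", bad[1, 2], ")")
  }

  asym <- abs(adjacency - t(adjacency))
  scale <- max(abs(adjacency), 1)
  if (max(asym) > 0) {
    if (max(asym) / scale <= asym_tol) {
      warning("adjacency numerically asymmetric (max rel. deviation ",
              signif(max(asym) / scale, 3), "); symmetrised as (A + t(A))/2")
      adjacency <- (adjacency + t(adjacency)) / 2
    } else {
      bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
      stop("adjacency is asymmetric beyond tolerance at entry (",
           bad[1], ",", bad[2], "): ", adjacency[bad[1], bad[2]], " vs ",
           adjacency[bad[2], bad[1]])
    }
  }
  if (any(diag(adjacency) != 0)) {
    warning("adjacency has nonzero diagonal; self-connections set to zero")
    diag(adjacency) <- 0
  }

  if (is.null(region_labels)) {
    region_labels <- rownames(adjacency)
    if (is.null(region_labels)) region_labels <- paste0("region_", seq_len(R))
  }
  if (length(region_labels) != R) {
    stop("region_labels length ", length(region_labels),
         " does not match ", R, " regions")
  }
  if (anyDuplicated(region_labels)) {
    stop("region_labels must be unique; duplicated: ",
         paste(unique(region_labels[duplicated(region_labels)]), collapse = ", "))
  }

  if (is.null(volumes)) volumes <- rep(1, R)
  if (length(volumes) != R) {
    stop("volumes length ", length(volumes), " does not match ", R, " regions")
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("volumes must be strictly positive and finite")
  }
  if (!is.null(names(volumes))) {
    if (!setequal(names(volumes), region_labels)) {
      stop("volume names do not match region labels")
    }
    volumes <- volumes[region_labels]
  }
  if (is.null(reference_volume)) reference_volume <- max(volumes)
  if (!is.finite(reference_volume) || reference_volume <= 0) {
    stop("reference_volume must be a positive scalar")
  }

  dimnames(adjacency) <- list(region_labels, region_labels)
  structure(
    list(adjacency = adjacency,
         volumes = stats::setNames(as.numeric(volumes), region_labels),
         region_labels = region_labels,
         reference_volume = reference_volume),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>", length(x$region_labels), "regions,",
      sum(x$adjacency[upper.tri(x$adjacency)] > 0), "edges\n")
  invisible(x)
}

#' Element-wise mean of several adjacency matrices
#'
#' Tractography pipelines produce one streamline matrix per scanned
#' individual; a common way to obtain a single group connectome is the
#' element-wise mean across individuals. All matrices must share dimensions
#' (and, when named, region labels).
#'
#' @param adjacencies List of square numeric matrices (or `connectome`
#'   objects, whose adjacency is used).
#' @return A single averaged adjacency matrix.
#' @export
mean_adjacency <- function(adjacencies) {
  if (length(adjacencies) == 0) stop("need at least one adjacency matrix")
  mats <- lapply(adjacencies, function(a) {
    if (inherits(a, "connectome")) a$adjacency else as.matrix(a)
  })
  dims <- vapply(mats, function(m) dim(m), integer(2))
  if (any(dims != dims[1, 1])) stop("all adjacency matrices must be square with equal dimension")
  labelled <- Filter(function(m) !is.null(rownames(m)), mats)
  if (length(labelled) > 1) {
    ref <- rownames(labelled[[1]])
    for (m in labelled[-1]) {
      if (!identical(rownames(m), ref)) stop("region labels differ between adjacency matrices")
    }
  }
  Reduce(`+`, mats) / length(mats)
}

#' Build the (unweighted) graph Laplacian of a connectome
#'
#' Returns `L = D - A` where `D = diag(A %*% 1)` is the degree matrix. Rows
#' of `L` sum to zero and off-diagonal entries are nonpositive; transport on
#' the network is governed by this operator (after volume weighting, see
#' [volume_weight()]).
#'
#' @param conn A [connectome()].
#' @return An object of class `laplacian` with fields `matrix`, `weighted`
#'   (`FALSE`), and `region_labels`.
#' @examples
#' conn <- connectome(matrix(c(0, 1, 1, 0), 2))
#' build_laplacian(conn)$matrix
#' @export
build_laplacian <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  A <- conn$adjacency
  L <- diag(rowSums(A), nrow = nrow(A)) - A
  dimnames(L) <- dimnames(A)
  structure(
    list(matrix = L, weighted = FALSE, region_labels = conn$region_labels),
    class = "laplacian"
  )
}

#' @export
print.laplacian <- function(x, ...) {
  cat("<laplacian>", nrow(x$matrix), "regions,",
      if (x$weighted) "volume-weighted" else "unweighted", "\n")
  invisible(x)
}

#' Weight a graph Laplacian by regional volumes
#'
#' Computes the volume-weighted Laplacian `Lw = V^{-1} L` with
#' `V = diag(v / vr)`, where `v` are regional volumes and `vr` the reference
#' volume. The weighting makes the transport term respect mass conservation
#' across regions of different size: the volume-weighted total signal
#' `sum_i v_i s_i` is conserved under pure diffusion.
#'
#' @param laplacian An unweighted [build_laplacian()] result.
#' @param conn The [connectome()] providing volumes (labels must match).
#' @return A `laplacian` object with `weighted = TRUE`.
#' @export
volume_weight <- function(laplacian, conn) {
  stopifnot(inherits(laplacian, "laplacian"), inherits(conn, "connectome"))
  if (laplacian$weighted) stop("laplacian is already volume-weighted")
  if (!identical(laplacian$region_labels, conn$region_labels)) {
    stop("region labels of laplacian and connectome differ")
  }
  v <- conn$volumes
  if (any(v <= 0)) stop("volumes must be strictly positive")
  w <- conn$reference_volume / v  # V^{-1} diagonal
  Lw <- laplacian$matrix * w      # row scaling
  structure(
    list(matrix = Lw, weighted = TRUE, region_labels = laplacian$region_labels),
    class = "laplacian"
  )
}

#' Group-average normalised regional volumes
#'
#' For each subject `n`, regional volumes are normalised by that subject's
#' maximum initial regional volume, then averaged across subjects:
#' `v_i = mean_n(v_i^n / max_j v_j^n)`. Every entry of the result lies in
#' (0, 1].
#'
#' @param per_subject_volumes List of positive numeric vectors, one per
#'   subject, all the same length (and consistently named, when named).
#' @return Numeric vector of group-normalised volumes.
#' @examples
#' group_normalised_volumes(list(c(2, 4), c(1, 1)))
#' @export
group_normalised_volumes <- function(per_subject_volumes) {
  if (length(per_subject_volumes) == 0) stop("no subject volumes supplied")
  lens <- vapply(per_subject_volumes, length, integer(1))
  if (any(lens != lens[1])) stop("all subjects must report the same number of regions")
  mats <- vapply(per_subject_volumes, function(v) {
    if (any(!is.finite(v)) || any(v <= 0)) stop("volumes must be positive and finite")
    v / max(v)
  }, numeric(lens[1]))
  out <- rowMeans(matrix(mats, nrow = lens[1]))
  nm <- names(per_subject_volumes[[1]])
  if (!is.null(nm)) names(out) <- nm
  out
}
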