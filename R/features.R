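#' Feature-extraction parameters
#'
#' Bundles the tunable constants of the substrate features.
#'
#' @param gr_radius neighbourhood radius, in normalized mm, for the
#'   activation-gradient pairing (default 7, the scale of clinical
#'   deceleration zones).
#' @param gr_min_dist pairs closer than this (mm) are skipped, never divided
#'   by (default 0.1).
#' @param gr_prob quantile of the per-point gradients used as the scalar GR
#'   summary (default 0.95; robust to a single extreme pair).
#' @param tail_frac width of the extreme tail that defines critical
#'   voltage-discrepancy points and late potentials, as a fraction of the
#'   channel range (default 0.2 — "the last 20% between the maximum and
#'   minimum values").
#' @param scar_cutoff dense-scar bipolar threshold in mV (default 0.5).
#' @param min_cluster minimum number of faces a cluster must contain to count
#'   as an area (default 3).
#' @param link_radius two occupied critical faces belong to the same cluster
#'   when their face-grid distance is at most this (default 4: the expected
#'   face spacing of a ~1500-point map on 14,400 faces is
#'   sqrt(14400/1500) = 3.1 cells and the isolation probability
#'   exp(-occupancy * 2r(r+1)) only drops below 2\% at r = 4, so contiguous
#'   substrate forms single clusters at design density; 1 gives strict edge
#'   adjacency).
#' @param vlt_measure \code{"signed"} (default) thresholds the upper tail of
#'   bipolar minus unipolar voltage, which flags unipolar depression with
#'   preserved bipolar voltage (intramural substrate); \code{"abs"} uses the
#'   absolute discrepancy instead.
#' @param late_direction \code{"latest"} (default) takes the latest
#'   \code{tail_frac} of the activation-time range as late potentials;
#'   \code{"earliest"} reverses the direction.
#' @param late_denominator \code{"non_late"} (default) expresses the late
#'   extent as a percentage of the non-late occupied faces (and may then
#'   exceed 100); \code{"total"} uses all occupied faces.
#' @param reference_rms RMS radius for [canonical_orientation()].
#' @return a list of class \code{feature_params}.
#' @export
feature_params <- function(gr_radius = 7, gr_min_dist = 0.1, gr_prob = 0.95,
                           tail_frac = 0.2, scar_cutoff = 0.5,
                           min_cluster = 3L, link_radius = 4L,
                           vlt_measure = c("signed", "abs"),
                           late_direction = c("latest", "earliest"),
                           late_denominator = c("non_late", "total"),
                           reference_rms = 30) {
  stopifnot(gr_radius > 0, gr_min_dist > 0, gr_prob > 0, gr_prob <= 1,
            tail_frac > 0, tail_frac < 1, scar_cutoff > 0,
            min_cluster >= 1, link_radius >= 1, reference_rms > 0)
  structure(list(gr_radius = gr_radius, gr_min_dist = gr_min_dist,
                 gr_prob = gr_prob, tail_frac = tail_frac,
                 scar_cutoff = scar_cutoff,
                 min_cluster = as.integer(min_cluster),
                 link_radius = as.integer(link_radius),
                 vlt_measure = match.arg(vlt_measure),
                 late_direction = match.arg(late_direction),
                 late_denominator = match.arg(late_denominator),
                 reference_rms = reference_rms),
            class = "feature_params")
}

#' Cluster occupied faces on the sphere grid
#'
#' Connected components of the given faces under the face-grid metric: two
#' faces are linked when their grid distance (bands + wrapped sectors) is at
#' most \code{link_radius}.
#'
#' @param faces integer vector of face indices.
#' @param sphere a \code{sphere_model}.
#' @param link_radius linking distance in grid steps.
#' @return integer vector of cluster ids (1..k) parallel to \code{faces}.
#' @export
cluster_faces <- function(faces, sphere, link_radius = 4L) {
  k <- length(faces)
  if (k == 0L) return(integer(0))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(k - 1L)) {
    d <- face_grid_distance(rep(faces[i], k - i), faces[(i + 1L):k], sphere)
    for (j in which(d <= link_radius)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, unique(roots))
}

# faces (within `member` subset) that belong to clusters of >= min_cluster
counted_cluster_faces <- function(member, fmap, sphere, params) {
  idx <- which(member)
  if (length(idx) == 0L) return(logical(length(member)))
  cl <- cluster_faces(fmap$face[idx], sphere, params$link_radius)
  sizes <- tabulate(cl)
  keep <- sizes[cl] >= params$min_cluster
  out <- logical(length(member))
  out[idx[keep]] <- TRUE
  out
}

regional_percent <- function(numer_mask, denom_mask, region) {
  vapply(1:8, function(r) {
    den <- sum(denom_mask & region == r)
    if (den == 0L) return(NA_real_)
    100 * sum(numer_mask & region == r) / den
  }, numeric(1))
}

#' Activation-gradient (deceleration-zone) value
#'
#' For every point, the maximal ratio of the absolute activation-time
#' difference to the Euclidean distance over all neighbours within
#' \code{gr_radius}; high values mark zones where very early and very late
#' activation meet over a short distance. The scalar GR summary is the
#' \code{gr_prob} quantile of the per-point values and the regional value is
#' the regional maximum.
#'
#' @param points data.frame with \code{x, y, z} (normalized mm) and
#'   \code{lat} (ms).
#' @param params a [feature_params()] list.
#' @param region optional integer vector (1..8) giving the sphere region of
#'   each point; enables the regional summaries.
#' @return list with \code{per_point} (ms/mm, 0 for isolated points),
#'   \code{scalar} and \code{regional} (length 8, NA for empty regions).
#' @export
gradient_value <- function(points, params = feature_params(), region = NULL) {
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points with activation times")
  X <- as.matrix(points[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(X))
  L <- abs(outer(points$lat, points$lat, "-"))
  ratio <- L / D
  ratio[D > params$gr_radius | D < params$gr_min_dist] <- -Inf
  diag(ratio) <- -Inf
  gr <- unname(apply(ratio, 1, max))
  gr[!is.finite(gr)] <- 0          # no admissible neighbour
  scalar <- unname(stats::quantile(gr, params$gr_prob, type = 7))
  regional <- rep(NA_real_, 8)
  if (!is.null(region)) {
    for (r in 1:8) {
      sel <- which(region == r)
      if (length(sel)) regional[r] <- max(gr[sel])
    }
  }
  list(per_point = gr, scalar = scalar, regional = regional)
}

extent_from_masks <- function(critical, fmap, sphere, params, denom_mask) {
  counted <- counted_cluster_faces(critical, fmap, sphere, params)
  den <- sum(denom_mask)
  scalar <- if (den == 0L) NA_real_ else 100 * sum(counted) / den
  list(scalar = scalar,
       regional = regional_percent(counted, denom_mask, fmap$region),
       critical = critical, counted = counted)
}

#' Voltage-discrepancy (VLT) extent
#'
#' Per occupied face the bipolar minus unipolar discrepancy is computed
#' (signed by default, see [feature_params()]); faces in the upper
#' \code{tail_frac} of its range are critical, critical faces are clustered
#' by grid proximity, and clusters of at least \code{min_cluster} faces count
#' toward the extent, a percentage of occupied faces. Regional values use the
#' same global threshold and clusters, restricted to each region.
#'
#' @param fmap a \code{face_value_map}.
#' @param sphere the \code{sphere_model} used for projection.
#' @param params a [feature_params()] list.
#' @return list with \code{scalar}, \code{regional} (length 8),
#'   \code{critical} and \code{counted} logical masks over occupied faces.
#' @export
vlt_extent <- function(fmap, sphere, params = feature_params()) {
  n <- length(fmap$face)
  if (n < 2L) {
    warning("fewer than 2 occupied faces: VLT undefined")
    return(list(scalar = NA_real_, regional = rep(NA_real_, 8),
                critical = logical(n), counted = logical(n)))
  }
  d <- fmap$values$bip_v - fmap$values$uni_v
  if (params$vlt_measure == "abs") d <- abs(d)
  rng <- max(d) - min(d)
  critical <- if (rng == 0) rep(FALSE, n) else
    d > min(d) + (1 - params$tail_frac) * rng
  extent_from_masks(critical, fmap, sphere, params, rep(TRUE, n))
}

#' Late-potential (LAT) extent
#'
#' Faces whose activation time falls in the latest \code{tail_frac} of the
#' activation-time range are late potentials; adjacent late faces form delay
#' areas and counted areas are expressed, by default, as a percentage of the
#' non-late occupied faces.
#'
#' @inheritParams vlt_extent
#' @return as [vlt_extent()].
#' @export
late_extent <- function(fmap, sphere, params = feature_params()) {
  n <- length(fmap$face)
  if (n < 2L) {
    warning("fewer than 2 occupied faces: late extent undefined")
    return(list(scalar = NA_real_, regional = rep(NA_real_, 8),
                critical = logical(n), counted = logical(n)))
  }
  lat <- fmap$values$lat
  rng <- max(lat) - min(lat)
  late <- if (rng == 0) rep(FALSE, n) else if (params$late_direction == "latest")
    lat > min(lat) + (1 - params$tail_frac) * rng
  else
    lat < min(lat) + params$tail_frac * rng
  denom <- if (params$late_denominator == "non_late") !late else rep(TRUE, n)
  if (sum(denom) == 0L) {
    warning("no faces in the late-extent denominator")
    return(list(scalar = NA_real_, regional = rep(NA_real_, 8),
                critical = late, counted = logical(n)))
  }
  extent_from_masks(late, fmap, sphere, params, denom)
}

#' Scar-area extent
#'
#' Faces with bipolar voltage below the dense-scar cutoff (0.5 mV) are low
#' amplitude; clustered low-amplitude faces form scar areas whose counted
#' extent is a percentage of occupied faces.
#'
#' @inheritParams vlt_extent
#' @return as [vlt_extent()].
#' @export
scar_extent <- function(fmap, sphere, params = feature_params()) {
  n <- length(fmap$face)
  if (n < 2L) {
    warning("fewer than 2 occupied faces: scar extent undefined")
    return(list(scalar = NA_real_, regional = rep(NA_real_, 8),
                critical = logical(n), counted = logical(n)))
  }
  scar <- fmap$values$bip_v < params$scar_cutoff
  extent_from_masks(scar, fmap, sphere, params, rep(TRUE, n))
}

#' Regional mean impedance
#'
#' @inheritParams vlt_extent
#' @return numeric length 8, mean impedance (ohm) of the occupied faces per
#'   region; NA for empty regions.
#' @export
regional_impedance <- function(fmap, sphere, params = feature_params()) {
  vapply(1:8, function(r) {
    sel <- fmap$region == r
    if (!any(sel)) return(NA_real_)
    mean(fmap$values$imp[sel])
  }, numeric(1))
}

#' Names of the feature-vector columns
#' @return character vector of the 44 feature names.
#' @export
feature_names <- function() {
  c("GR", paste0("GR", 1:8),
    "VLT", paste0("VLT", 1:8),
    "LAT", paste0("LAT", 1:8),
    "ScarAreas", paste0("Scar", 1:8),
    paste0("IMP", 1:8))
}

#' Extract the full substrate feature vector of one patient
#'
#' Orchestrates the normalization and feature stages: canonical orientation
#' (rotation + size normalization), projection onto the tessellated sphere,
#' then activation gradient, voltage discrepancy, late-potential extent, scar
#' areas and regional impedance, globally and per region.
#'
#' @param export an \code{eam_export}.
#' @param sphere a \code{sphere_model} (default [build_sphere()]).
#' @param params a [feature_params()] list.
#' @param canonical apply [canonical_orientation()] first (default TRUE).
#' @return one-row data.frame with columns [feature_names()]; attribute
#'   \code{diagnostics} records the collision count.
#' @export
extract_features <- function(export, sphere = build_sphere(),
                             params = feature_params(), canonical = TRUE) {
  if (canonical)
    export <- canonical_orientation(export, reference_rms = params$reference_rms)
  fmap <- project_points(export, sphere)

  pt_region <- sphere$region[fmap$point_face]
  gr <- gradient_value(export$points, params, region = pt_region)
  vlt <- vlt_extent(fmap, sphere, params)
  late <- late_extent(fmap, sphere, params)
  scar <- scar_extent(fmap, sphere, params)
  imp <- regional_impedance(fmap, sphere, params)

  out <- as.data.frame(as.list(stats::setNames(
    c(gr$scalar, gr$regional,
      vlt$scalar, vlt$regional,
      late$scalar, late$regional,
      scar$scalar, scar$regional,
      imp),
    feature_names())))
  attr(out, "diagnostics") <- list(n_collisions = fmap$n_collisions,
                                   n_occupied = length(fmap$face))
  out
}
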