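#' Rotate and rescale a point cloud into the canonical frame
#'
#' Hearts are mapped in arbitrary positions, orientations and sizes, so maps
#' from different patients are only comparable after normalization. The cloud
#' is centered on its centroid and rotated so that the principal axes of the
#' position covariance align with a canonical frame: longest axis to z,
#' second axis to x, third to y (right-handed, determinant +1 always — no
#' reflection). Sign conventions are data-driven and deterministic: +z points
#' toward the hemisphere where activation is latest (an apex proxy, since the
#' apico-basal direction carries the dominant activation trend) and +x toward
#' the hemisphere with higher mean unipolar voltage. If a channel is constant
#' the sign falls back to making the largest-magnitude component of the axis
#' positive.
#'
#' The cloud is finally rescaled so that its root-mean-square distance from
#' the centroid equals \code{reference_rms}, completing the size part of the
#' normalization; all downstream distance-based features (notably the
#' activation gradient) are computed in these normalized millimetres, making
#' the full feature vector invariant to rigid motion and uniform scaling of
#' the input.
#'
#' @param export an \code{eam_export}.
#' @param reference_rms RMS radius of the normalized cloud, in mm
#'   (default 30, a typical mapped left-ventricular scale).
#' @param rescale set \code{FALSE} to keep the original scale.
#' @return the export with positions replaced by canonical coordinates;
#'   attributes \code{rotation} (3 x 3, rows = canonical axes),
#'   \code{centroid} and \code{scale} record the applied transform.
#' @export
canonical_orientation <- function(export, reference_rms = 30, rescale = TRUE) {
  stopifnot(inherits(export, "eam_export"))
  pts <- export$points
  X <- as.matrix(pts[, c("x", "y", "z")])
  if (nrow(X) < 4L) stop("need at least 4 points to orient a cloud")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  cv <- crossprod(Xc) / nrow(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[3] <= max(eg$values[1], 1) * 1e-10)
    stop("degenerate point cloud: rank < 3, cannot orient")
  zax <- eg$vectors[, 1]   # long axis
  xax <- eg$vectors[, 2]

  zax <- fix_axis_sign(zax, Xc, pts$lat)
  xax <- fix_axis_sign(xax, Xc, pts$uni_v)
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],   # y = z x x, right-handed
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  R <- rbind(x = xax, y = yax, z = zax)

  Xn <- Xc %*% t(R)
  s <- 1
  if (rescale) {
    rms <- sqrt(mean(rowSums(Xn^2)))
    if (rms <= 0) stop("degenerate point cloud: zero extent")
    s <- reference_rms / rms
    Xn <- Xn * s
  }
  pts$x <- Xn[, 1]; pts$y <- Xn[, 2]; pts$z <- Xn[, 3]
  out <- eam_export(pts, patient_id = export$patient_id,
                    metadata = export$metadata)
  attr(out, "rotation") <- R
  attr(out, "centroid") <- ctr
  attr(out, "scale") <- s
  out
}

# Orient `axis` so the projection of the cloud onto it correlates positively
# with `channel`; constant channel -> largest-|component|-positive fallback.
fix_axis_sign <- function(axis, Xc, channel) {
  proj <- drop(Xc %*% axis)
  cs <- sum(proj * (channel - mean(channel)))
  if (abs(cs) > 1e-12) {
    if (cs < 0) axis <- -axis
  } else {
    k <- which.max(abs(axis))
    if (axis[k] < 0) axis <- -axis
  }
  axis
}

#' Project mapping points onto the tessellated sphere
#'
#' The centroid of the point cloud is placed at the sphere center and every
#' point is projected radially from the centroid onto the surface, landing in
#' the face that contains its direction. Each face holds at most one point;
#' when two or more points fall in the same face the one whose direction is
#' closest to the face center is kept and the collision is counted (the face
#' count is chosen so collisions are rare on clinical maps).
#'
#' @param export an \code{eam_export} (normally already passed through
#'   [canonical_orientation()]).
#' @param sphere a \code{sphere_model}.
#' @return object of class \code{face_value_map}: \code{face} (sorted indices
#'   of occupied faces), \code{point} (source point index per occupied face),
#'   \code{values} (data.frame of uni_v, bip_v, lat, imp per occupied face),
#'   \code{region} (region per occupied face), \code{point_face} (containing
#'   face of every input point, including collision losers),
#'   \code{n_points}, \code{n_collisions}.
#' @export
project_points <- function(export, sphere) {
  stopifnot(inherits(export, "eam_export"), inherits(sphere, "sphere_model"))
  pts <- export$points
  X <- as.matrix(pts[, c("x", "y", "z")])
  if (nrow(X) < 4L) stop("need at least 4 points to project")
  ctr <- colMeans(X)
  D <- sweep(X, 2, ctr)
  nrm <- sqrt(rowSums(D^2))
  if (all(nrm < 1e-9)) stop("all points coincide with the centroid")
  keep <- nrm >= 1e-9
  if (!all(keep)) {
    warning(sum(!keep), " point(s) coincide with the centroid and were dropped")
    D <- D[keep, , drop = FALSE]; nrm <- nrm[keep]
  }
  dirs <- D / nrm
  faces <- face_of_direction(dirs, sphere)

  # collision resolution: keep the point closest (in angle) to the face center
  dot <- rowSums(dirs * sphere$centers[faces, , drop = FALSE])
  ord <- order(faces, -dot, seq_along(faces))
  first <- !duplicated(faces[ord])
  winner <- ord[first]
  winner <- winner[order(faces[winner])]
  n_coll <- length(faces) - length(winner)
  if (n_coll > 0)
    warning(n_coll, " projection collision(s): face already occupied, ",
            "kept the point nearest the face center")

  point_idx <- which(keep)[winner]
  occ_faces <- faces[winner]
  structure(
    list(face = occ_faces,
         point = point_idx,
         values = pts[point_idx, c("uni_v", "bip_v", "lat", "imp")],
         region = sphere$region[occ_faces],
         point_face = {
           pf <- rep(NA_integer_, nrow(pts)); pf[keep] <- faces; pf
         },
         n_points = nrow(pts),
         n_collisions = n_coll),
    class = "face_value_map")
}

#' @export
print.face_value_map <- function(x, ...) {
  cat(sprintf("face_value_map: %d occupied faces from %d points (%d collision(s))\n",
              length(x$face), x$n_points, x$n_collisions))
  invisible(x)
}

#' Serialize a face-value map as sparse TSV
#'
#' One row per occupied face and channel: \code{face_index, channel, value}.
#'
#' @param fmap a \code{face_value_map}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_face_map <- function(fmap, path) {
  stopifnot(inherits(fmap, "face_value_map"))
  long <- do.call(rbind, lapply(names(fmap$values), function(ch)
    data.frame(face_index = fmap$face, channel = ch,
               value = fmap$values[[ch]])))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
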