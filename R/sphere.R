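#' Build the fixed equal-area sphere tessellation
#'
#' Constructs the reference sphere used to spatially normalize mapping point
#' clouds. The surface is cut into \code{n_bands} latitudinal bands of uniform
#' height in the z-coordinate and \code{n_lon} longitude sectors of uniform
#' width. By Archimedes' hat-box theorem every cell of this grid has exactly
#' the same area (\eqn{4\pi R^2 / (n_{bands} n_{lon})}), so the default
#' 120 x 120 grid yields the canonical 14,400 equal-area faces. Cell lookup
#' from a direction is O(1).
#'
#' Faces are indexed row-major: face \code{(b, l)} (band \code{b} counted from
#' the north pole \code{z = +1}, sector \code{l} counted from longitude 0) has
#' index \code{(b - 1) * n_lon + l}. Edge-sharing neighbours are the two
#' sectors beside it (wrapping in longitude) and the aligned faces in the
#' bands above and below.
#'
#' @param n_bands number of z-uniform latitudinal bands (default 120).
#' @param n_lon number of longitude sectors (default 120).
#' @param radius sphere radius; the sphere is a normalized reference shape, so
#'   the default is 1 (dimensionless).
#' @param region_map named integer vector mapping octant sign codes
#'   (\code{"+++"}, \code{"-+-"}, ... for the signs of x, y, z of the face
#'   center) to region indices 1-8; see [region_labels()]. The default mapping
#'   is a documented geometric convention and can be remapped for real anatomy.
#' @return an object of class \code{sphere_model} with elements
#'   \code{n_bands}, \code{n_lon}, \code{n_faces}, \code{radius},
#'   \code{centers} (n_faces x 3 unit directions), \code{areas},
#'   \code{band}, \code{lon} (per-face grid coordinates),
#'   \code{region} (per-face region index 1-8) and \code{region_map}.
#' @examples
#' sph <- build_sphere()
#' sph$n_faces                      # 14400
#' range(sph$areas) * sph$n_faces   # both 4*pi
#' table(sph$region)                # 1800 faces per region
#' @export
build_sphere <- function(n_bands = 120L, n_lon = 120L, radius = 1,
                         region_map = default_region_map()) {
  n_bands <- as.integer(n_bands); n_lon <- as.integer(n_lon)
  if (n_bands < 1L || n_lon < 1L) stop("n_bands and n_lon must be positive")
  stopifnot(is.numeric(radius), radius > 0)
  check_region_map(region_map)

  n_faces <- n_bands * n_lon
  dz   <- 2 / n_bands
  dlon <- 2 * pi / n_lon

  band <- rep(seq_len(n_bands), each = n_lon)
  lon  <- rep(seq_len(n_lon), times = n_bands)

  zc   <- 1 - (band - 0.5) * dz            # band midpoint in z
  lamc <- (lon - 0.5) * dlon               # sector midpoint longitude
  rxy  <- sqrt(pmax(0, 1 - zc^2))
  centers <- cbind(x = rxy * cos(lamc), y = rxy * sin(lamc), z = zc)

  # hat-box: area of each cell is dz * dlon * R^2, identical for all faces
  areas <- rep(dz * dlon * radius^2, n_faces)

  code <- paste0(ifelse(centers[, 1] >= 0, "+", "-"),
                 ifelse(centers[, 2] >= 0, "+", "-"),
                 ifelse(centers[, 3] >= 0, "+", "-"))
  region <- unname(region_map[code])

  structure(
    list(n_bands = n_bands, n_lon = n_lon, n_faces = n_faces,
         radius = radius, centers = centers, areas = areas,
         band = band, lon = lon, region = region, region_map = region_map),
    class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("sphere_model: %d faces (%d bands x %d sectors), radius %g\n",
              x$n_faces, x$n_bands, x$n_lon, x$radius))
  cat(sprintf("face area: %.6g (all equal), regions: %s\n",
              x$areas[1], paste(tabulate(x$region, 8), collapse = "/")))
  invisible(x)
}

#' Anatomical labels of the eight sphere regions
#'
#' The sphere is partitioned into eight octants of the canonical frame, each
#' carrying the label of the macro-cardiac projection region it stands for.
#' Labels are nominal: no image registration is performed, so regions are
#' geometric octants with anatomical names.
#'
#' @return named character vector, names "1".."8".
#' @export
region_labels <- function() {
  c("1" = "anterior sub-mitral",
    "2" = "posterior mid-apical",
    "3" = "antero-septal mitro-aortic valvular",
    "4" = "postero-septal mid-apical",
    "5" = "antero-lateral sub-valvular mitro-aortic",
    "6" = "postero-lateral mid-basal",
    "7" = "antero-lateral mid-basal",
    "8" = "apical and infero-apical mid-apical")
}

#' Default octant-to-region lookup
#'
#' Sign codes give the signs of the (x, y, z) components of a face center in
#' the canonical frame (+z apical, +x anterior, +y septal). The assignment of
#' labels to octants is a fixed convention, configurable in [build_sphere()].
#'
#' @return named integer vector of length 8.
#' @export
default_region_map <- function() {
  c("+++" = 8L, "+-+" = 2L, "-++" = 4L, "--+" = 7L,
    "++-" = 3L, "+--" = 1L, "-+-" = 6L, "---" = 5L)
}

check_region_map <- function(region_map) {
  codes <- c("+++", "+-+", "-++", "--+", "++-", "+--", "-+-", "---")
  if (!all(codes %in% names(region_map)))
    stop("region_map must name all eight octant sign codes")
  if (!setequal(as.integer(region_map), 1:8))
    stop("region_map must be a bijection onto region indices 1..8")
  invisible(TRUE)
}

#' Locate the face containing each direction
#'
#' @param dirs n x 3 matrix of (not necessarily unit) direction vectors.
#' @param sphere a \code{sphere_model}.
#' @return integer vector of face indices.
#' @export
face_of_direction <- function(dirs, sphere) {
  dirs <- rbind(dirs)
  nrm <- sqrt(rowSums(dirs^2))
  if (any(nrm == 0)) stop("zero direction vector has no containing face")
  z <- dirs[, 3] / nrm
  band <- pmin(sphere$n_bands, pmax(1L, floor((1 - z) / (2 / sphere$n_bands)) + 1L))
  lam <- atan2(dirs[, 2], dirs[, 1]) %% (2 * pi)
  lonk <- pmin(sphere$n_lon, floor(lam / (2 * pi / sphere$n_lon)) + 1L)
  as.integer((band - 1L) * sphere$n_lon + lonk)
}

#' Region index of sphere faces
#'
#' @param face_index integer face indices.
#' @param sphere a \code{sphere_model}.
#' @return integer region indices in 1..8.
#' @export
region_of <- function(face_index, sphere) {
  face_index <- as.integer(face_index)
  if (any(is.na(face_index)) || any(face_index < 1L | face_index > sphere$n_faces))
    stop("invalid face index")
  sphere$region[face_index]
}

#' Edge-sharing neighbours of a face
#'
#' @param face_index a single face index.
#' @param sphere a \code{sphere_model}.
#' @return integer vector of neighbouring face indices (2 at a polar band
#'   when the grid has a single sector, otherwise 3 or 4).
#' @export
face_neighbors <- function(face_index, sphere) {
  b <- sphere$band[face_index]; l <- sphere$lon[face_index]
  nl <- sphere$n_lon
  nb <- integer(0)
  if (nl > 1L) {
    nb <- c(nb, (b - 1L) * nl + (l %% nl) + 1L,
                (b - 1L) * nl + ((l - 2L) %% nl) + 1L)
  }
  if (b > 1L) nb <- c(nb, (b - 2L) * nl + l)
  if (b < sphere$n_bands) nb <- c(nb, b * nl + l)
  unique(as.integer(nb))
}

#' Grid (face-graph) distance between faces
#'
#' The face adjacency graph is a band x sector grid that wraps in longitude;
#' its shortest-path metric is the Manhattan distance with wrapped sector
#' difference. Used to decide cluster connectivity.
#'
#' @param f1,f2 integer vectors of face indices (recycled).
#' @param sphere a \code{sphere_model}.
#' @return integer vector of graph distances.
#' @export
face_grid_distance <- function(f1, f2, sphere) {
  b1 <- sphere$band[f1]; b2 <- sphere$band[f2]
  l1 <- sphere$lon[f1];  l2 <- sphere$lon[f2]
  dl <- abs(l1 - l2)
  dl <- pmin(dl, sphere$n_lon - dl)
  abs(b1 - b2) + dl
}

#' Centroid direction of a region
#'
#' Unit vector pointing at the mean of the face centers of a region; used by
#' the synthetic generator to place patches inside a target region.
#'
#' @param sphere a \code{sphere_model}.
#' @param region region index 1..8.
#' @return length-3 unit vector.
#' @export
region_centroid <- function(sphere, region) {
  stopifnot(region %in% 1:8)
  v <- colMeans(sphere$centers[sphere$region == region, , drop = FALSE])
  v / sqrt(sum(v^2))
}
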