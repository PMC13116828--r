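#' @title Mapping-point export input/output
#' @description
#' The native export formats of clinical mapping systems are proprietary, so
#' the package defines a plain tab-separated dialect carrying the per-point
#' fields an operator can export: position (mm), three catheter-orientation
#' angles (degrees), unipolar and bipolar voltage (mV), local activation time
#' (ms, relative to the map reference, may be negative) and impedance (ohm).
#' Files are diff-able and trivially produced from real exports.
#' @name eam_io
NULL

EXPORT_COLUMNS <- c("x", "y", "z", "alpha", "beta", "gamma",
                    "uni_v", "bip_v", "lat", "imp")

#' Construct a mapping export object
#'
#' @param points data.frame with the columns \code{x, y, z, alpha, beta,
#'   gamma, uni_v, bip_v, lat, imp} (one row per acquired endocardial point,
#'   acquisition order preserved).
#' @param patient_id non-empty identifier string.
#' @param metadata named character list of free-form key/value pairs.
#' @return object of class \code{eam_export}.
#' @export
eam_export <- function(points, patient_id = "anonymous", metadata = list()) {
  points <- as.data.frame(points)
  missing_cols <- setdiff(EXPORT_COLUMNS, names(points))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  points <- points[EXPORT_COLUMNS]
  if (nrow(points) < 1L) stop("an export must contain at least one point")
  if (!nzchar(patient_id)) stop("patient_id must be non-empty")
  for (cl in EXPORT_COLUMNS) {
    v <- points[[cl]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("column '", cl, "' must be finite numeric")
  }
  if (any(points$uni_v < 0) || any(points$bip_v < 0))
    stop("voltages must be non-negative")
  if (any(points$imp <= 0)) stop("impedance must be positive")
  structure(list(patient_id = patient_id, points = points,
                 metadata = metadata),
            class = "eam_export")
}

#' @export
print.eam_export <- function(x, ...) {
  cat(sprintf("eam_export '%s': %d points\n", x$patient_id, nrow(x$points)))
  cat(sprintf("  bipolar %.2f-%.2f mV, unipolar %.2f-%.2f mV, LAT %.1f-%.1f ms\n",
              min(x$points$bip_v), max(x$points$bip_v),
              min(x$points$uni_v), max(x$points$uni_v),
              min(x$points$lat), max(x$points$lat)))
  invisible(x)
}

#' Write a mapping export as tab-separated text
#'
#' Header row \code{x y z alpha beta gamma uni_v bip_v lat imp}; every value
#' printed with six decimals. A \code{.gz} extension triggers transparent
#' gzip compression.
#'
#' @param export an \code{eam_export}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_export <- function(export, path) {
  stopifnot(inherits(export, "eam_export"))
  pts <- export$points
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  lines <- c(paste(EXPORT_COLUMNS, collapse = "\t"),
             do.call(paste, c(lapply(pts, function(v) sprintf("%.6f", v)),
                              sep = "\t")))
  writeLines(lines, con)
  invisible(path)
}

#' Read a mapping export written by [write_export()]
#'
#' @param path input path (\code{.gz} handled transparently).
#' @param patient_id identifier to attach; defaults to the file stem.
#' @return an \code{eam_export}.
#' @export
read_export <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) stop("empty export file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(EXPORT_COLUMNS, header)
  if (length(missing_cols))
    stop("missing column(s) in header: ", paste(missing_cols, collapse = ", "))
  if (length(lines) < 2L) stop("export has a header but no data rows")
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  n <- length(body)
  mat <- matrix(NA_real_, n, length(header), dimnames = list(NULL, header))
  for (i in seq_len(n)) {
    row <- suppressWarnings(as.numeric(body[[i]]))
    if (length(row) != length(header) || any(is.na(row)))
      stop("non-numeric or malformed data in row ", i)
    mat[i, ] <- row
  }
  if (is.null(patient_id))
    patient_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  eam_export(as.data.frame(mat)[EXPORT_COLUMNS], patient_id = patient_id)
}
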