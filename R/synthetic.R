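#' Define a synthetic substrate scenario
#'
#' Describes one synthetic left ventricle for the map generator: an
#' ellipsoidal shell of mapped points plus planted substrate abnormalities.
#' Channels are statistical surrogates (no biophysical electrogram
#' simulation); patches emulate the substrate classes seen clinically —
#' dense scar (depressed bipolar voltage), delay areas (late activation),
#' intramural substrate (unipolar depression with preserved bipolar voltage)
#' and a conduction isthmus (a steep activation ramp).
#'
#' The shell semi-axes are assigned long to z, middle to x, short to y, so
#' the generation frame coincides with the canonical frame recovered by
#' [canonical_orientation()]. Baselines include a mild apico-basal activation
#' slope and a small unipolar trend along x; both are physiologic and pin the
#' canonical sign convention.
#'
#' @param n_points number of mapped points (default 1500).
#' @param shell_radii semi-axes (long, mid, short) in mm; distinct values
#'   keep the principal axes well defined (default \code{c(40, 32, 26)}).
#' @param scar_patches list of patches \code{list(region =, radius_deg =,
#'   mean = )}: bipolar voltage inside the patch is shifted additively so its
#'   mean becomes \code{mean} mV (patch effects compose additively).
#' @param late_patches list of \code{list(region =, radius_deg =, offset = )}
#'   adding \code{offset} ms to activation times inside the patch.
#' @param vlt_patches list of \code{list(region =, radius_deg =,
#'   depression = )} subtracting \code{depression} mV from unipolar voltage
#'   inside the patch (bipolar untouched).
#' @param isthmus optional \code{list(region =, width_mm =, step_ms = )}: a
#'   linear activation ramp of height \code{step_ms} over \code{width_mm},
#'   confined to a 22-degree cap at the region centroid (kept clear of the
#'   region border so the planted gradient stays inside the target region).
#' @param noise_sd named per-channel Gaussian noise SDs
#'   (\code{uni}, \code{bip} mV, \code{lat} ms, \code{imp} ohm).
#' @param baseline named healthy-channel parameters: \code{uni}, \code{bip}
#'   (mV), \code{lat0} (ms), \code{lat_slope} (ms/mm along z),
#'   \code{uni_x_slope} (mV/mm along x), \code{imp} (ohm).
#' @param jitter_sd radial jitter SD in mm (default 1).
#' @param seed integer; the same seed and scenario give a bit-identical map.
#' @return a list of class \code{substrate_scenario}.
#' @export
substrate_scenario <- function(n_points = 1500L,
                               shell_radii = c(40, 32, 26),
                               scar_patches = list(),
                               late_patches = list(),
                               vlt_patches = list(),
                               isthmus = NULL,
                               noise_sd = c(uni = 0.5, bip = 0.3,
                                            lat = 3, imp = 5),
                               baseline = list(uni = 8, bip = 3, lat0 = -20,
                                               lat_slope = 0.3,
                                               uni_x_slope = 0.03, imp = 100),
                               jitter_sd = 1,
                               seed = 1L) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points <= 0L) stop("n_points must be positive")
  stopifnot(length(shell_radii) == 3, all(shell_radii > 0))
  check_patch <- function(p, field) {
    stopifnot(is.list(p), p$region %in% 1:8)
    if (!is.null(p$radius_deg) && p$radius_deg <= 0)
      stop("patch angular radius must be positive")
    if (is.null(p[[field]])) stop("patch missing field '", field, "'")
  }
  for (p in scar_patches) check_patch(p, "mean")
  for (p in late_patches) check_patch(p, "offset")
  for (p in vlt_patches) check_patch(p, "depression")
  if (!is.null(isthmus)) {
    stopifnot(isthmus$region %in% 1:8, isthmus$width_mm > 0)
  }
  nd <- c(uni = 0.5, bip = 0.3, lat = 3, imp = 5)
  nd[names(noise_sd)] <- noise_sd
  bl <- list(uni = 8, bip = 3, lat0 = -20, lat_slope = 0.3,
             uni_x_slope = 0.03, imp = 100)
  bl[names(baseline)] <- baseline
  structure(list(n_points = n_points, shell_radii = shell_radii,
                 scar_patches = scar_patches, late_patches = late_patches,
                 vlt_patches = vlt_patches, isthmus = isthmus,
                 noise_sd = nd, baseline = bl, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "substrate_scenario")
}

# Area-uniform sample of n directions/points on the ellipsoid surface
# (rejection against the surface-element density).
sample_ellipsoid <- function(n, radii) {
  a <- radii[2]; b <- radii[3]; cc <- radii[1]   # x, y, z semi-axes
  mmax <- max(a * b, a * cc, b * cc)
  U <- matrix(numeric(0), 0, 3)
  while (nrow(U) < n) {
    m <- ceiling((n - nrow(U)) * 1.6) + 16
    g <- matrix(stats::rnorm(3 * m), m, 3)
    g <- g / sqrt(rowSums(g^2))
    w <- sqrt((g[, 1] * b * cc)^2 + (g[, 2] * a * cc)^2 + (g[, 3] * a * b)^2)
    U <- rbind(U, g[stats::runif(m) < w / mmax, , drop = FALSE])
  }
  U <- U[seq_len(n), , drop = FALSE]
  cbind(x = a * U[, 1], y = b * U[, 2], z = cc * U[, 3])
}

#' Generate a synthetic mapping export
#'
#' Samples points area-uniformly on the scenario's ellipsoidal shell, adds
#' radial jitter, fills the six channels from the healthy baselines plus
#' noise, then applies the planted patches. Patch membership is decided by
#' geodesic angular distance between the point's direction (from the shell
#' center) and the patch center, placed at the centroid direction of the
#' target region; overlapping patch effects compose additively.
#'
#' @param scenario a [substrate_scenario()].
#' @param sphere optional \code{sphere_model} used only to locate region
#'   centroids (default [build_sphere()]).
#' @return an \code{eam_export}; attribute \code{planted} records the ground
#'   truth (per-point patch membership masks and the isthmus region) for
#'   validation studies.
#' @export
generate_map <- function(scenario, sphere = build_sphere()) {
  stopifnot(inherits(scenario, "substrate_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_points
  bl <- scenario$baseline; nd <- scenario$noise_sd

  P <- sample_ellipsoid(n, scenario$shell_radii)
  if (scenario$jitter_sd > 0) {
    nrm <- sqrt(rowSums(P^2))
    P <- P * (1 + stats::rnorm(n, 0, scenario$jitter_sd) / nrm)
  }
  dirs <- P / sqrt(rowSums(P^2))

  uni <- bl$uni + bl$uni_x_slope * P[, 1] + stats::rnorm(n, 0, nd[["uni"]])
  bip <- bl$bip + stats::rnorm(n, 0, nd[["bip"]])
  lat <- bl$lat0 + bl$lat_slope * P[, 3] + stats::rnorm(n, 0, nd[["lat"]])
  imp <- bl$imp + stats::rnorm(n, 0, nd[["imp"]])

  in_patch <- function(p) {
    ctr <- region_centroid(sphere, p$region)
    ang <- acos(pmin(1, pmax(-1, drop(dirs %*% ctr))))
    ang <= p$radius_deg * pi / 180
  }
  planted <- list(scar = rep(FALSE, n), late = rep(FALSE, n),
                  vlt = rep(FALSE, n), isthmus_region = NA_integer_)
  for (p in scenario$scar_patches) {
    m <- in_patch(p)
    bip[m] <- bip[m] + (p$mean - bl$bip)
    planted$scar <- planted$scar | m
  }
  for (p in scenario$late_patches) {
    m <- in_patch(p)
    lat[m] <- lat[m] + p$offset
    planted$late <- planted$late | m
  }
  for (p in scenario$vlt_patches) {
    m <- in_patch(p)
    uni[m] <- uni[m] - p$depression
    planted$vlt <- planted$vlt | m
  }
  if (!is.null(scenario$isthmus)) {
    is <- scenario$isthmus
    ctr <- region_centroid(sphere, is$region)
    ang <- acos(pmin(1, pmax(-1, drop(dirs %*% ctr))))
    cap <- ang <= 22 * pi / 180
    # tangent direction at the cap center, ramp coordinate in mm
    tang <- c(-ctr[2], ctr[1], 0)
    if (sqrt(sum(tang^2)) < 1e-6) tang <- c(1, 0, 0)
    tang <- tang / sqrt(sum(tang^2))
    s <- drop(P %*% tang)
    ramp <- pmin(1, pmax(0, (s + is$width_mm / 2) / is$width_mm))
    lat[cap] <- lat[cap] + is$step_ms * ramp[cap]
    planted$isthmus_region <- is$region
  }

  pts <- data.frame(
    x = P[, 1], y = P[, 2], z = P[, 3],
    alpha = stats::runif(n, 0, 360), beta = stats::runif(n, 0, 360),
    gamma = stats::runif(n, 0, 360),
    uni_v = pmax(0, uni), bip_v = pmax(0, bip), lat = lat,
    imp = pmax(1, imp))
  out <- eam_export(pts, patient_id = sprintf("synthetic-%06d", scenario$seed),
                    metadata = list(source = "synthetic"))
  attr(out, "planted") <- planted
  out
}

#' Distributions of the synthetic clinical covariates
#'
#' One row per covariate: type (\code{continuous}/\code{binary}/
#' \code{ordinal}), distribution parameters and truncation bounds. The set is
#' the union of covariates a structural-heart ablation cohort records
#' (symptom class, echo, labs, comorbidity and history flags) and is
#' extensible: rows can be added or edited before passing the table to
#' [generate_clinical()].
#'
#' @return data.frame with columns \code{name, type, mean, sd, prob, lower,
#'   upper}.
#' @export
clinical_variable_specs <- function() {
  con <- function(name, mean, sd, lower = -Inf, upper = Inf)
    data.frame(name = name, type = "continuous", mean = mean, sd = sd,
               prob = NA_real_, lower = lower, upper = upper)
  bin <- function(name, prob)
    data.frame(name = name, type = "binary", mean = NA_real_, sd = NA_real_,
               prob = prob, lower = NA_real_, upper = NA_real_)
  rbind(
    data.frame(name = "NYHA", type = "ordinal", mean = NA_real_,
               sd = NA_real_, prob = NA_real_, lower = 1, upper = 4),
    con("PAP", 30, 8, lower = 10),          # systolic pulmonary artery pressure, mmHg
    con("TAPSE", 20, 4, lower = 5),         # mm
    con("LVEF", 45, 12, lower = 10, upper = 75),  # %
    con("iLVEDV", 80, 25, lower = 30),      # mL/m2
    con("Creatinine", 1.0, 0.3, lower = 0.3),     # mg/dL
    con("BMI", 26, 4, lower = 15),          # kg/m2
    bin("Sex", 0.7),                        # male
    bin("Hypertension", 0.5),
    bin("HFrEF", 0.35),
    bin("HFpEF", 0.15),
    bin("Diabetes", 0.20),
    bin("COPD", 0.12),
    bin("AF", 0.25),
    bin("ArrhythmicStorm", 0.15),
    bin("TWaveInversion", 0.30),
    bin("StrokeTIA", 0.08),
    bin("FamilyHistorySCD", 0.10),
    bin("ParoxysmalVT", 0.30),
    bin("LVAneurysm", 0.10),
    bin("ValvularCardiopathy", 0.15))
}

# direct-draw distributions of the substrate scalars, for modeling studies
# that bypass map generation (scales match typical extracted values)
feature_scalar_specs <- function() {
  data.frame(name = c("GR", "LAT", "VLT", "ScarAreas"),
             mean = c(2, 30, 20, 15), sd = c(1, 15, 10, 10),
             lower = 0)
}

rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic clinical covariate table
#'
#' Draws every covariate of [clinical_variable_specs()] independently from
#' its documented distribution (NYHA uniform on 1-4; continuous measures
#' truncated normal; binaries Bernoulli at the stated prevalence) and
#' optionally injects missing values completely at random.
#'
#' @param n_patients number of patients.
#' @param seed integer seed.
#' @param missing_rate per-cell probability of a missing value (default 0).
#' @param include_features also draw the substrate scalars GR, LAT, VLT and
#'   ScarAreas directly from their stated distributions (for isolated
#'   modeling studies; in the full pipeline these come from
#'   [extract_features()]).
#' @param specs covariate specification table (default
#'   [clinical_variable_specs()]).
#' @return data.frame with a \code{patient_id} column and one column per
#'   covariate.
#' @export
generate_clinical <- function(n_patients, seed = 1L, missing_rate = 0,
                              include_features = FALSE,
                              specs = clinical_variable_specs()) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients <= 0L) stop("n_patients must be positive")
  stopifnot(missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  out <- data.frame(patient_id = sprintf("P%05d", seq_len(n_patients)))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    out[[s$name]] <- switch(s$type,
      ordinal = sample(seq(s$lower, s$upper), n_patients, replace = TRUE),
      continuous = rtruncnorm1(n_patients, s$mean, s$sd, s$lower, s$upper),
      binary = stats::rbinom(n_patients, 1, s$prob),
      stop("unknown covariate type: ", s$type))
  }
  if (include_features) {
    fs <- feature_scalar_specs()
    for (i in seq_len(nrow(fs)))
      out[[fs$name[i]]] <- rtruncnorm1(n_patients, fs$mean[i], fs$sd[i],
                                       fs$lower[i])
  }
  if (missing_rate > 0) {
    for (cl in setdiff(names(out), "patient_id")) {
      miss <- stats::runif(n_patients) < missing_rate
      out[[cl]][miss] <- NA
    }
  }
  out
}

#' Generative outcome model for major arrhythmic events
#'
#' A logistic model on the linear predictor scale. The default reuses the
#' fitted clinical polynomial (symptom class, pulmonary pressure,
#' late-potential extent, activation gradient, hypertension) as generative
#' truth, so simulation-and-refit studies have a known target.
#'
#' @param intercept logit units.
#' @param coefficients named numeric vector, logit units per unit covariate.
#' @return a list of class \code{outcome_model}.
#' @export
outcome_model <- function(intercept = -21.007,
                          coefficients = c(NYHA = 3.889, PAP = 0.262,
                                           LAT = 0.034, GR = 0.492,
                                           Hypertension = 2.638)) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients))
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be named")
  structure(list(intercept = intercept, coefficients = coefficients),
            class = "outcome_model")
}

#' Assign binary outcomes from a generative logistic model
#'
#' \eqn{P(MAE = 1) = logistic(intercept + \sum_j \beta_j x_j)}; outcomes are
#' Bernoulli draws at that probability.
#'
#' @param cohort data.frame containing every covariate named in the model.
#' @param model an [outcome_model()].
#' @param seed integer seed.
#' @return the cohort with added columns \code{MAE} (0/1); the generative
#'   probabilities are attached as attribute \code{p_mae}.
#' @export
assign_outcomes <- function(cohort, model = outcome_model(), seed = 1L) {
  stopifnot(inherits(model, "outcome_model"))
  missing_vars <- setdiff(names(model$coefficients), names(cohort))
  if (length(missing_vars))
    stop("coefficient name(s) not in cohort: ",
         paste(missing_vars, collapse = ", "))
  X <- as.matrix(cohort[names(model$coefficients)])
  if (any(is.na(X))) stop("covariates used by the outcome model must be complete")
  eta <- model$intercept + drop(X %*% model$coefficients)
  p <- stats::plogis(eta)
  set.seed(seed)
  cohort$MAE <- stats::rbinom(nrow(cohort), 1, p)
  attr(cohort, "p_mae") <- p
  cohort
}
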