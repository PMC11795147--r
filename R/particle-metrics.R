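## Recognised mineral classes. Thickness rules differ by class; serpentine
## has its own cylindrical surface-area formula and no thickness rule.
MINERAL_CLASSES <- c("serpentine", "amphibole_asbestiform_or_mixed",
                     "erionite", "balangeroite", "fibrous_talc",
                     "other_nonserpentine")

check_mineral_class <- function(mineral_class) {
  bad <- setdiff(unique(mineral_class), MINERAL_CLASSES)
  if (length(bad))
    stop("unknown mineral_class: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(MINERAL_CLASSES, collapse = ", "), ")")
  invisible(mineral_class)
}

#' DCC coefficient set
#'
#' Container for the five coefficients of the Dimensional Coefficient of
#' Carcinogenicity, `DCC = 1 - exp(-A * SA^K / (B * W^T + C))`. The default
#' instance holds the fitted values A = 0.11, K = 1, B = 1000, T = 3, C = 1.
#'
#' @param A,K,B,T,C positive dimensionless coefficients.
#' @return An object of class `dcc_params` (a named list).
#' @examples
#' dcc_params()
#' dcc_params(A = 0.2, T = 2.5)
#' @export
dcc_params <- function(A = 0.11, K = 1, B = 1000, T = 3, C = 1) {
  vals <- c(A = A, K = K, B = B, T = T, C = C)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all DCC coefficients must be finite and > 0")
  structure(as.list(vals), class = "dcc_params")
}

#' @export
print.dcc_params <- function(x, ...) {
  cat("DCC coefficients: A =", x$A, " K =", x$K, " B =", x$B,
      " T =", x$T, " C =", x$C, "\n")
  invisible(x)
}

#' Particle thickness from width
#'
#' Empirical thickness rules by mineral class: erionite `Th = W`,
#' balangeroite `W/1.1`, fibrous talc `W/3`, asbestiform and mixed
#' amphiboles `log10(Th) = 0.692 log10(W) - 0.493`, any other
#' non-serpentine class `W/1.9`. Thickness is undefined for serpentine,
#' whose surface area is computed directly from the cylindrical model.
#'
#' @param width width in micrometres (> 0); vectorised.
#' @param mineral_class one of [MINERAL_CLASSES] except `"serpentine"`;
#'   recycled against `width`.
#' @return thickness in micrometres.
#' @examples
#' emp_thickness(1, "amphibole_asbestiform_or_mixed")  # 10^-0.493
#' emp_thickness(1.9, "other_nonserpentine")           # 1
#' @export
emp_thickness <- function(width, mineral_class) {
  check_mineral_class(mineral_class)
  if (any(!is.finite(width)) || any(width <= 0))
    stop("width must be finite and > 0")
  if (any(mineral_class == "serpentine"))
    stop("thickness undefined for serpentine")
  n <- max(length(width), length(mineral_class))
  width <- rep_len(width, n)
  mineral_class <- rep_len(mineral_class, n)
  th <- numeric(n)
  th[mineral_class == "erionite"]     <- width[mineral_class == "erionite"]
  th[mineral_class == "balangeroite"] <- width[mineral_class == "balangeroite"] / 1.1
  th[mineral_class == "fibrous_talc"] <- width[mineral_class == "fibrous_talc"] / 3
  amph <- mineral_class == "amphibole_asbestiform_or_mixed"
  th[amph] <- 10^(0.692 * log10(width[amph]) - 0.493)
  oth <- mineral_class == "other_nonserpentine"
  th[oth] <- width[oth] / 1.9
  th
}

#' Particle surface area
#'
#' Surface area in square micrometres. For serpentine particles the
#' cylinder-with-hemispherical-caps model `0.5*pi*W^2 + pi*W*L` is used;
#' for every other class the rectangular-prism model
#' `2LW + 2L*Th + 2W*Th` with class-specific thickness.
#'
#' @param length,width particle dimensions in micrometres (> 0); vectorised.
#' @param mineral_class mineral class, recycled.
#' @param thickness optional explicit thickness (micrometres), overriding the
#'   empirical rule (useful for sensitivity work and testing).
#' @return surface area in square micrometres.
#' @examples
#' emp_surface_area(10, 1, "serpentine")                       # 10.5 * pi
#' emp_surface_area(11.4, 0.35, "amphibole_asbestiform_or_mixed")
#' @export
emp_surface_area <- function(length, width, mineral_class, thickness = NULL) {
  check_mineral_class(mineral_class)
  if (any(!is.finite(length)) || any(length <= 0) ||
      any(!is.finite(width)) || any(width <= 0))
    stop("length and width must be finite and > 0")
  n <- max(base::length(length), base::length(width), base::length(mineral_class))
  length <- rep_len(length, n); width <- rep_len(width, n)
  mineral_class <- rep_len(mineral_class, n)
  sa <- numeric(n)
  serp <- mineral_class == "serpentine"
  sa[serp] <- 0.5 * pi * width[serp]^2 + pi * width[serp] * length[serp]
  if (any(!serp)) {
    th <- if (is.null(thickness)) {
      emp_thickness(width[!serp], mineral_class[!serp])
    } else rep_len(thickness, n)[!serp]
    sa[!serp] <- 2 * length[!serp] * width[!serp] +
      2 * length[!serp] * th + 2 * width[!serp] * th
  }
  sa
}

#' Aerodynamic diameter of an elongate particle
#'
#' Timbrell's relation `AD = 66 * W * (AR / (2 + 4 AR))^2.2 * (rho/rho0)^0.5`
#' where `AR` is the aspect ratio and `rho` the particle density. For any
#' finite aspect ratio the value is below the `AR -> Inf` supremum
#' `66 * W * 0.25^2.2 * sqrt(rho/rho0)`.
#'
#' @param width width in micrometres (> 0).
#' @param aspect_ratio length/width, at least 1.
#' @param density particle density in g/cm^3 (> 0).
#' @param rho0 reference density, 1.0 g/cm^3 by default.
#' @return aerodynamic diameter in micrometres.
#' @examples
#' emp_aerodynamic_diameter(1, 3, 1)   # 66 * (3/14)^2.2
#' @export
emp_aerodynamic_diameter <- function(width, aspect_ratio, density, rho0 = 1.0) {
  if (any(!is.finite(width)) || any(width <= 0))
    stop("width must be finite and > 0")
  if (any(!is.finite(aspect_ratio)) || any(aspect_ratio < 1))
    stop("aspect_ratio must be finite and >= 1")
  if (any(!is.finite(density)) || any(density <= 0) || rho0 <= 0)
    stop("density must be finite and > 0")
  66 * width * (aspect_ratio / (2 + 4 * aspect_ratio))^2.2 *
    sqrt(density / rho0)
}

#' Criteria-particle discriminant score
#'
#' The per-particle discriminant `2.99 log10(L) - 5.82 log10(W) - 3.80`.
#' Particles scoring at or above zero are "criteria particles", the
#' dimensional signature associated with asbestiform habit.
#'
#' @param length,width particle dimensions in micrometres (> 0).
#' @return the score (dimensionless); see [is_criteria_particle()].
#' @examples
#' emp_criteria_score(10, 0.25)  # about 2.69, a criteria particle
#' emp_criteria_score(10, 1.0)   # -0.81, not a criteria particle
#' @export
emp_criteria_score <- function(length, width) {
  if (any(!is.finite(length)) || any(length <= 0) ||
      any(!is.finite(width)) || any(width <= 0))
    stop("length and width must be finite and > 0")
  2.99 * log10(length) - 5.82 * log10(width) - 3.80
}

#' @rdname emp_criteria_score
#' @export
is_criteria_particle <- function(length, width) {
  emp_criteria_score(length, width) >= 0
}

#' Dimensional Coefficient of Carcinogenicity (DCC)
#'
#' `DCC = 1 - exp(-A * SA^K / (B * W^T + C))`, a dimensionless score in
#' `[0, 1)` increasing with surface area and, beyond the optimal width,
#' decreasing with width. With the default coefficients this is
#' `1 - exp(-0.11 * SA / (1000 * W^3 + 1))`.
#'
#' @param surface_area surface area in square micrometres (>= 0).
#' @param width width in micrometres (> 0).
#' @param params a [dcc_params()] object.
#' @return DCC value(s) in `[0, 1)`.
#' @examples
#' emp_dcc(13.47, 0.31)  # about 0.047
#' @export
emp_dcc <- function(surface_area, width, params = dcc_params()) {
  stopifnot(inherits(params, "dcc_params"))
  if (any(!is.finite(surface_area)) || any(surface_area < 0))
    stop("surface_area must be finite and >= 0")
  if (any(!is.finite(width)) || any(width <= 0))
    stop("width must be finite and > 0")
  1 - exp(-params$A * surface_area^params$K /
            (params$B * width^params$T + params$C))
}

#' Compute all derived per-particle metrics
#'
#' Adds derived columns to a particle table: `aspect_ratio`, `thickness`
#' (NA for serpentine), `surface_area`, `aerodynamic_diameter`,
#' `criteria_score`, `criteria` (logical) and `dcc`.
#'
#' @param particles data frame with columns `length_um`, `width_um` and
#'   optionally `mineral_class` (default `"other_nonserpentine"`) and
#'   `density` (default looked up from [mineral_config()] when a `mineral`
#'   column is present, else 3.0 g/cm^3, the tremolite value).
#' @param params a [dcc_params()] object for the DCC column.
#' @return the input data frame with derived columns appended.
#' @export
particle_metrics <- function(particles, params = dcc_params()) {
  stopifnot(is.data.frame(particles))
  req <- c("length_um", "width_um")
  miss <- setdiff(req, names(particles))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!nrow(particles)) {
    for (cl in c("aspect_ratio", "thickness", "surface_area",
                 "aerodynamic_diameter", "criteria_score", "dcc"))
      particles[[cl]] <- numeric(0)
    particles$criteria <- logical(0)
    return(particles)
  }
  if (is.null(particles$mineral_class))
    particles$mineral_class <- "other_nonserpentine"
  if (is.null(particles$density)) {
    particles$density <- if (!is.null(particles$mineral)) {
      cfg <- mineral_config()
      d <- cfg$density_g_cm3[match(tolower(particles$mineral), cfg$mineral)]
      ifelse(is.na(d), 3.0, d)
    } else 3.0
  }
  L <- particles$length_um; W <- particles$width_um
  cls <- particles$mineral_class
  particles$aspect_ratio <- L / W
  th <- rep(NA_real_, length(L))
  nons <- cls != "serpentine"
  if (any(nons)) th[nons] <- emp_thickness(W[nons], cls[nons])
  particles$thickness <- th
  particles$surface_area <- emp_surface_area(L, W, cls)
  particles$aerodynamic_diameter <-
    emp_aerodynamic_diameter(W, pmax(particles$aspect_ratio, 1), particles$density)
  particles$criteria_score <- emp_criteria_score(L, W)
  particles$criteria <- particles$criteria_score >= 0
  particles$dcc <- emp_dcc(particles$surface_area, W, params)
  particles
}
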