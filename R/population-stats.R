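## Counting-rule filter profiles. Length bound is strict (>), width and
## aspect-ratio bounds inclusive, matching the counting rules the indices
## are defined on.
FILTER_PROFILES <- list(
  main_emp       = list(min_length = 5, min_width = 0.05, max_width = 3,
                        min_aspect_ratio = 3),
  pearson        = list(min_length = 2, min_width = 0.05, max_width = 3,
                        min_aspect_ratio = 3),
  empa_numerator = list(min_length = 5, min_width = 0.05, max_width = 3,
                        min_aspect_ratio = 3, max_width_numerator = 0.15),
  ar5_main       = list(min_length = 5, min_width = 0.05, max_width = 3,
                        min_aspect_ratio = 5),
  ar5_pearson    = list(min_length = 2, min_width = 0.05, max_width = 3,
                        min_aspect_ratio = 5)
)

#' Counting-rule filter profiles
#'
#' Named dimensional windows used throughout: `main_emp` (L > 5 um,
#' 0.05 <= W <= 3 um, AR >= 3) for criteria fraction, EMPA, DCC and
#' summaries; `pearson` (L > 2 um, same width window, AR >= 3) for the
#' Pearson index; `empa_numerator` additionally W <= 0.15 um; `ar5_*` are
#' the aspect-ratio >= 5 variants.
#'
#' @param name profile name.
#' @return a list of bounds.
#' @export
filter_profile <- function(name = c("main_emp", "pearson", "empa_numerator",
                                    "ar5_main", "ar5_pearson")) {
  name <- match.arg(name)
  c(FILTER_PROFILES[[name]], list(name = name))
}

#' Filter a particle table by a counting-rule profile
#'
#' @param particles data frame with `length_um` and `width_um` columns.
#' @param profile a profile name or the result of [filter_profile()].
#' @return the subset of rows satisfying the profile (length bound strict,
#'   width and aspect-ratio bounds inclusive).
#' @examples
#' p <- data.frame(length_um = c(6, 4, 6, 6, 10),
#'                 width_um  = c(0.1, 0.1, 2.5, 3.5, 0.04))
#' emp_filter(p, "main_emp")  # only the first row survives every rule
#' @export
emp_filter <- function(particles, profile = "main_emp") {
  stopifnot(is.data.frame(particles))
  if (is.character(profile)) profile <- filter_profile(profile)
  if (!nrow(particles)) return(particles)
  L <- particles$length_um; W <- particles$width_um
  if (any(!is.finite(L)) || any(L <= 0) || any(!is.finite(W)) || any(W <= 0))
    stop("particles must have positive finite dimensions")
  keep <- L > profile$min_length &
    W >= profile$min_width & W <= profile$max_width &
    L / W >= profile$min_aspect_ratio
  if (!is.null(profile$max_width_numerator))
    keep <- keep & W <= profile$max_width_numerator
  particles[keep, , drop = FALSE]
}

#' Pearson index of a particle population
#'
#' Pearson product-moment correlation between log10 length and log10 width
#' over the `pearson`-filtered subset (L > 2 um, 0.05 <= W <= 3 um,
#' AR >= 3). Near zero for asbestiform populations, where width is grown
#' independently of length; elevated for comminuted fragments. Also returns
#' the fibrosity regression `log10 W = F log10 L + C` fitted by OLS.
#'
#' @param particles particle data frame (unfiltered; the profile is applied
#'   internally).
#' @param profile filter profile, `"pearson"` by default (`"ar5_pearson"`
#'   for the aspect-ratio-5 variant).
#' @return list with `r`, `slope` (F), `intercept` (C) and `n`.
#' @export
pearson_index <- function(particles, profile = "pearson") {
  sub <- emp_filter(particles, profile)
  if (nrow(sub) < 3)
    stop("pearson_index needs at least 3 particles after filtering (got ",
         nrow(sub), ")")
  lL <- log10(sub$length_um); lW <- log10(sub$width_um)
  if (var(lL) == 0 || var(lW) == 0)
    stop("degenerate population: zero variance in logged dimensions")
  fit <- lm(lW ~ lL)
  list(r = cor(lL, lW), slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = nrow(sub))
}

geo_mean <- function(x) exp(mean(log(x)))
geo_sd <- function(x) exp(sd(log(x)))

#' Summarise a particle population
#'
#' Computes the population-level indices on a particle table: criteria
#' fraction, EMPA (fraction of main-window EMPs with width <= 0.15 um),
#' Pearson index, mean per-particle DCC, and arithmetic plus geometric
#' summaries of length, width, aspect ratio, aerodynamic diameter and
#' surface area. Criteria fraction, EMPA, DCC and dimensional summaries use
#' the `main_emp` window; the Pearson index uses the `pearson` window.
#'
#' @param particles particle data frame (`length_um`, `width_um`, optional
#'   `mineral_class`, `density`, `dataset_id`).
#' @param params a [dcc_params()] object.
#' @param ar5 if `TRUE`, use the aspect-ratio >= 5 windows throughout.
#' @return a one-row data frame (fields of a dataset summary).
#' @export
summarize_population <- function(particles, params = dcc_params(), ar5 = FALSE) {
  main_name <- if (ar5) "ar5_main" else "main_emp"
  pe_name <- if (ar5) "ar5_pearson" else "pearson"
  main <- emp_filter(particles, main_name)
  if (!nrow(main))
    stop("no particles survive the '", main_name, "' filter")
  m <- particle_metrics(main, params)
  pidx <- pearson_index(particles, pe_name)
  data.frame(
    dataset_id = if (!is.null(main$dataset_id)) main$dataset_id[1] else NA_character_,
    n_particles = nrow(m),
    criteria_fraction = mean(m$criteria),
    pearson_index = pidx$r,
    fibrosity_slope = pidx$slope,
    empa = mean(m$width_um <= 0.15),
    mean_dcc = mean(m$dcc),
    mean_length = mean(m$length_um), sd_length = sd(m$length_um),
    gm_length = geo_mean(m$length_um), gsd_length = geo_sd(m$length_um),
    mean_width = mean(m$width_um), sd_width = sd(m$width_um),
    gm_width = geo_mean(m$width_um), gsd_width = geo_sd(m$width_um),
    mean_ar = mean(m$aspect_ratio), sd_ar = sd(m$aspect_ratio),
    mean_ad = mean(m$aerodynamic_diameter), sd_ad = sd(m$aerodynamic_diameter),
    mean_sa = mean(m$surface_area), sd_sa = sd(m$surface_area),
    stringsAsFactors = FALSE)
}

#' Welch two-sample comparison of group values
#'
#' Two-sample t statistic with the Welch denominator
#' `sqrt(s1^2/n1 + s2^2/n2)` and Welch-Satterthwaite degrees of freedom;
#' group means and SDs use n - 1 denominators.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t_statistic`,
#'   `df`, `p_value` and a `degenerate` flag set when both groups have zero
#'   variance (infinite or undefined t).
#' @examples
#' group_ttest(c(1, 2, 3), c(4, 5, 6))
#' @export
group_ttest <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  out <- list(mean_a = mean(values_a), sd_a = sd(values_a),
              mean_b = mean(values_b), sd_b = sd(values_b))
  if (out$sd_a == 0 && out$sd_b == 0) {
    out$t_statistic <- if (out$mean_a == out$mean_b) 0 else
      sign(out$mean_a - out$mean_b) * Inf
    out$df <- NA_real_
    out$p_value <- if (out$mean_a == out$mean_b) 1 else 0
    out$degenerate <- TRUE
    return(out)
  }
  tt <- t.test(values_a, values_b, var.equal = FALSE)
  out$t_statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out$degenerate <- FALSE
  out
}
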