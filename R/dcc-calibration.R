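#' Fitting coefficient for DCC calibration
#'
#' `Coef = R * U_asb^(1/4) / U_nonasb^(1/2)`, the objective maximized when
#' selecting the DCC coefficients: R is the (multiple) correlation of the
#' potency regression on log biosolubility and log mean DCC, and U_asb,
#' U_nonasb are the mean DCC values of the asbestiform and non-asbestiform
#' testing particles. The powers weight the correlation most and reward
#' separation between habits.
#'
#' @param r correlation in \[-1, 1\].
#' @param u_asb mean asbestiform DCC (>= 0).
#' @param u_nonasb mean non-asbestiform DCC (> 0).
#' @return the coefficient (dimensionless).
#' @examples
#' fitting_coef(0.98, 0.046, 0.0034)  # about 7.78
#' @export
fitting_coef <- function(r, u_asb, u_nonasb) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) stop("r must be in [-1, 1]")
  if (any(u_asb < 0)) stop("u_asb must be >= 0")
  if (any(!is.finite(u_nonasb)) || any(u_nonasb <= 0))
    stop("u_nonasb must be > 0")
  r * u_asb^0.25 / u_nonasb^0.5
}

## Default Monte-Carlo search ranges for the DCC coefficients; B is held
## fixed at 1000 (only two of the three proportional coefficients are free).
DEFAULT_CAL_RANGES <- list(A = c(0.10, 2), K = c(1, 5), T = c(0.5, 5),
                           C = c(1, 10))

#' Evaluate the calibration objective at one coefficient vector
#'
#' Computes, for a candidate (A, K, T, C) with B fixed: the mean DCC of
#' each per-mineral population, the potency regression
#' `log10(R_M) ~ log10(biosolubility) + log10(mean DCC)`, the mean DCC of
#' the pooled asbestiform and non-asbestiform populations, and the
#' [fitting_coef()]. Candidates with a non-positive DCC slope or with
#' asbestiform mean DCC not exceeding the non-asbestiform mean are
#' rejected (`NA` objective): the published fit has positive coefficients
#' and asbestiform particles must score higher.
#'
#' @param params a [dcc_params()] candidate.
#' @param mineral_pops named list of per-mineral particle data frames
#'   (main-window).
#' @param mineral_refs data frame with `mineral`, `rm_percent`,
#'   `biosolubility_yr` matching `mineral_pops` names.
#' @param asb_pop,nonasb_pop pooled habit particle data frames.
#' @return list with `coef`, `r`, `u_asb`, `u_nonasb`, `mineral_dcc`.
#' @export
calibration_objective <- function(params, mineral_pops, mineral_refs,
                                  asb_pop, nonasb_pop) {
  stopifnot(inherits(params, "dcc_params"))
  md <- vapply(mineral_pops, function(p) {
    mean(emp_dcc(emp_surface_area(p$length_um, p$width_um, p$mineral_class),
                 p$width_um, params))
  }, numeric(1))
  ref <- mineral_refs[match(names(mineral_pops), mineral_refs$mineral), ]
  out <- list(coef = NA_real_, r = NA_real_, u_asb = NA_real_,
              u_nonasb = NA_real_, mineral_dcc = md)
  if (any(md <= 0)) return(out)
  fit <- refit_regression(log10(ref$rm_percent),
                          data.frame(bio = log10(ref$biosolubility_yr),
                                     dcc = log10(md)))
  out$r <- fit$r
  if (unname(fit$coefficients["dcc"]) <= 0) return(out)
  pop_dcc <- function(p)
    mean(emp_dcc(emp_surface_area(p$length_um, p$width_um, p$mineral_class),
                 p$width_um, params))
  out$u_asb <- pop_dcc(asb_pop)
  out$u_nonasb <- pop_dcc(nonasb_pop)
  if (out$u_asb <= out$u_nonasb) return(out)
  out$coef <- fitting_coef(sqrt(fit$r_squared), out$u_asb, out$u_nonasb)
  out
}

#' Monte-Carlo search for the DCC coefficients
#'
#' Draws `n_draws` coefficient vectors uniformly within `ranges` (B fixed),
#' evaluates [calibration_objective()] for each, and returns the
#' maximizer. Reproducible under `seed`; the full draw trace is returned
#' for diagnostics of the objective surface.
#'
#' @param mineral_pops,mineral_refs,asb_pop,nonasb_pop as in
#'   [calibration_objective()].
#' @param ranges named list of `c(lo, hi)` ranges for A, K, T, C.
#' @param n_draws number of random draws.
#' @param seed integer seed.
#' @param B fixed scale coefficient.
#' @return list with `params` (best [dcc_params()]), `coef`, `r`, `u_asb`,
#'   `u_nonasb`, `n_draws`, `seed` and `trace` (one row per draw).
#' @export
calibrate_dcc <- function(mineral_pops, mineral_refs, asb_pop, nonasb_pop,
                          ranges = DEFAULT_CAL_RANGES, n_draws = 2000,
                          seed = 1, B = 1000) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  for (nm in c("A", "K", "T", "C"))
    if (is.null(ranges[[nm]]) || diff(ranges[[nm]]) < 0)
      stop("invalid range for ", nm)
  if (!length(mineral_pops) || !nrow(asb_pop) || !nrow(nonasb_pop))
    stop("populations must be non-empty")
  set.seed(seed)
  draws <- data.frame(
    A = runif(n_draws, ranges$A[1], ranges$A[2]),
    K = runif(n_draws, ranges$K[1], ranges$K[2]),
    T = runif(n_draws, ranges$T[1], ranges$T[2]),
    C = runif(n_draws, ranges$C[1], ranges$C[2]))
  evals <- lapply(seq_len(n_draws), function(i) {
    p <- dcc_params(A = draws$A[i], K = draws$K[i], B = B,
                    T = draws$T[i], C = draws$C[i])
    calibration_objective(p, mineral_pops, mineral_refs, asb_pop, nonasb_pop)
  })
  draws$coef <- vapply(evals, `[[`, numeric(1), "coef")
  draws$r <- vapply(evals, `[[`, numeric(1), "r")
  draws$u_asb <- vapply(evals, `[[`, numeric(1), "u_asb")
  draws$u_nonasb <- vapply(evals, `[[`, numeric(1), "u_nonasb")
  if (all(is.na(draws$coef)))
    stop("no admissible draw: every candidate was rejected")
  best <- which.max(draws$coef)
  structure(list(
    params = dcc_params(A = draws$A[best], K = draws$K[best], B = B,
                        T = draws$T[best], C = draws$C[best]),
    coef = draws$coef[best], r = draws$r[best],
    u_asb = draws$u_asb[best], u_nonasb = draws$u_nonasb[best],
    n_draws = n_draws, seed = seed, trace = draws),
    class = "dcc_calibration")
}

#' @export
print.dcc_calibration <- function(x, ...) {
  cat("DCC Monte-Carlo calibration:", x$n_draws, "draws, seed", x$seed, "\n")
  cat("  best objective:", signif(x$coef, 4), " (R =", signif(x$r, 3),
      ", U_asb =", signif(x$u_asb, 3), ", U_nonasb =", signif(x$u_nonasb, 3), ")\n")
  print(x$params)
  invisible(x)
}

#' Standard synthetic calibration inputs
#'
#' Builds the synthetic stand-ins for the calibration data: one population
#' per reference mineral matching its tabulated width and surface area
#' ([synthetic_mineral_population()]), plus pooled asbestiform and
#' non-asbestiform tremolite populations from the testing-set specs.
#'
#' @param n_mineral particles per mineral population (pre-filter).
#' @param n_per_set particles per tremolite dataset.
#' @param seed integer seed.
#' @return list with `mineral_pops`, `mineral_refs`, `asb_pop`, `nonasb_pop`.
#' @export
calibration_populations <- function(n_mineral = 1500, n_per_set = 2000,
                                    seed = 1) {
  t4 <- emp_table("table4")
  mineral_pops <- lapply(seq_len(nrow(t4)), function(i)
    synthetic_mineral_population(t4$mineral[i], n = n_mineral, seed = seed + i))
  names(mineral_pops) <- t4$mineral
  specs <- default_population_specs(n = n_per_set, seed = seed + 100)
  t5 <- emp_table("table5")
  testing <- t5$dataset[t5$group == "testing"]
  pops <- lapply(specs[testing], function(s)
    emp_filter(generate_population(s), "main_emp"))
  habits <- vapply(specs[testing], `[[`, character(1), "habit")
  list(mineral_pops = mineral_pops,
       mineral_refs = data.frame(mineral = t4$mineral,
                                 rm_percent = t4$rm_percent,
                                 biosolubility_yr = t4$biosolubility_yr),
       asb_pop = do.call(rbind, pops[habits == "asbestiform"]),
       nonasb_pop = do.call(rbind, pops[habits == "non_asbestiform"]))
}
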