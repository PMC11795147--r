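#' EMPA-linear mesothelioma potency model
#'
#' `R_M = -0.012 + 0.011 * EMPA(%)`, with EMPA expressed in percent
#' (0-100). Negative values are reported verbatim and read as negligible
#' potency, the prediction for non-asbestiform populations.
#'
#' @param empa_percent EMPA in percent, in \[0, 100\].
#' @return mesothelioma potency factor R_M on the Hodgson-Darnton % scale.
#' @examples
#' potency_empa(64.8)  # 0.701
#' potency_empa(0)     # -0.012 (negligible)
#' @export
potency_empa <- function(empa_percent) {
  if (any(!is.finite(empa_percent)) || any(empa_percent < 0) ||
      any(empa_percent > 100))
    stop("empa_percent must be in [0, 100]")
  -0.012 + 0.011 * empa_percent
}

#' DCC + biosolubility mesothelioma potency model
#'
#' `log10(R_M) = 0.04 + 1.15 log10(Biosolubility) + 2.15 log10(DCC)`;
#' strictly increasing in both arguments.
#'
#' @param avg_dcc population-average DCC, in (0, 1).
#' @param biosolubility modelled fiber lifetime in biological fluid, years
#'   (> 0); 49 years is the tremolite value used for tremolite populations.
#' @return R_M on the Hodgson-Darnton % scale.
#' @examples
#' potency_dcc(0.11, 66)   # crocidolite, about 1.18
#' potency_dcc(0.138, 49)  # about 1.36
#' @export
potency_dcc <- function(avg_dcc, biosolubility) {
  if (any(!is.finite(avg_dcc)) || any(avg_dcc <= 0) || any(avg_dcc >= 1))
    stop("avg_dcc must be in (0, 1)")
  if (any(!is.finite(biosolubility)) || any(biosolubility <= 0))
    stop("biosolubility must be > 0")
  10^(0.04 + 1.15 * log10(biosolubility) + 2.15 * log10(avg_dcc))
}

#' Width maximizing the DCC expression
#'
#' For fixed surface area the DCC kernel `A * SA^K / (B * W^T + C)` has an
#' interior maximum in width (through the surface-area dependence of a
#' compact particle) at `W = (2KC / (B (T - 2K)))^(1/T)`, defined when
#' `T > 2K`. At the fitted coefficients this gives 0.126 um, the width of
#' theoretically maximal carcinogenic potency.
#'
#' @param params a [dcc_params()] object.
#' @return optimal width in micrometres.
#' @examples
#' optimal_width()  # (0.002)^(1/3), about 0.126
#' @export
optimal_width <- function(params = dcc_params()) {
  stopifnot(inherits(params, "dcc_params"))
  if (params$T <= 2 * params$K)
    stop("no interior maximum: requires T > 2K")
  (2 * params$K * params$C / (params$B * (params$T - 2 * params$K)))^(1 / params$T)
}

#' Membranolytic HC50 predicted from DCC
#'
#' `log10(HC50) = -1.06 + 17.12 * DCC`, with HC50 in fibers x 10^9 per ml.
#' Monotone increasing: higher-DCC fibers are less cytotoxic per fiber
#' (more fibers are needed to lyse half the erythrocytes) even as their
#' mesothelioma potency rises.
#'
#' @param avg_dcc population-average DCC in \[0, 1).
#' @return HC50 in fibers x 10^9 / ml.
#' @examples
#' hc50_from_dcc(0)      # 10^-1.06
#' hc50_from_dcc(0.068)  # about 1.27
#' @export
hc50_from_dcc <- function(avg_dcc) {
  if (any(!is.finite(avg_dcc)) || any(avg_dcc < 0) || any(avg_dcc >= 1))
    stop("avg_dcc must be in [0, 1)")
  10^(-1.06 + 17.12 * avg_dcc)
}

#' Relative potency in rats from human potency
#'
#' `Relative potency in rats = 1.26 + 0.48 * log10(R_M)`, linking the
#' Hodgson-Darnton human potency scale to relative mesothelioma potency
#' after intrapleural instillation in Wistar rats.
#'
#' @param rm_percent R_M on the Hodgson-Darnton % scale (> 0).
#' @return relative potency (dimensionless).
#' @examples
#' rat_relative_potency(0.059)  # tremolite, 0.67
#' @export
rat_relative_potency <- function(rm_percent) {
  if (any(!is.finite(rm_percent)) || any(rm_percent <= 0))
    stop("rm_percent must be > 0")
  1.26 + 0.48 * log10(rm_percent)
}

#' Ordinary least-squares refit with multiple correlation
#'
#' Refits any of the printed regressions from tabulated inputs. Reports the
#' coefficient vector, the (multiple) correlation R signed by the first
#' predictor's slope for single-predictor fits, R^2, the overall-fit F-test
#' p-value, and n.
#'
#' @param y response values.
#' @param x data frame or matrix of predictors.
#' @param log_y,log_x apply log10 to the response / to all predictors.
#' @return list with `coefficients`, `r`, `r_squared`, `p_value`, `n`.
#' @examples
#' refit_regression(c(1, 2, 3, 4.1), data.frame(x = 1:4))
#' @export
refit_regression <- function(y, x, log_y = FALSE, log_x = FALSE) {
  x <- as.data.frame(x)
  if (log_y) y <- log10(y)
  if (log_x) x[] <- lapply(x, log10)
  n <- length(y)
  if (n <= ncol(x) + 1)
    stop("need n greater than number of predictors + 1")
  dat <- cbind(.y = y, x)
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)
  if (any(is.na(coef(fit))))
    warning("collinear predictors: some coefficients not estimable")
  r2 <- sm$r.squared
  r <- sqrt(r2)
  if (ncol(x) == 1) r <- r * sign(coef(fit)[2])
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  list(coefficients = coef(fit), r = unname(r), r_squared = r2,
       p_value = p, n = n)
}

#' Predict mesothelioma potency for dataset summaries
#'
#' Applies the EMPA-linear and DCC-based models to population summaries and
#' reports both estimates and their mean. EMPA is stored as a fraction and
#' enters the linear model in percent.
#'
#' @param summaries data frame with columns `empa` (fraction) and
#'   `mean_dcc`, e.g. rows from [summarize_population()].
#' @param biosolubility biosolubility in years for the DCC model (tremolite
#'   default, 49).
#' @return the input with `rm_empa`, `rm_dcc`, `rm_mean` and a
#'   `negligible` flag (negative EMPA-model potency) appended.
#' @export
predict_potency <- function(summaries, biosolubility = 49) {
  stopifnot(is.data.frame(summaries),
            all(c("empa", "mean_dcc") %in% names(summaries)))
  summaries$rm_empa <- potency_empa(100 * summaries$empa)
  summaries$rm_dcc <- potency_dcc(summaries$mean_dcc, biosolubility)
  summaries$rm_mean <- (summaries$rm_empa + summaries$rm_dcc) / 2
  summaries$negligible <- summaries$rm_empa < 0
  summaries
}
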