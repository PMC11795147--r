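## Fixed published decision boundary in (Pearson index, criteria fraction)
## space: asbestiform iff CF >= 0.58 * PI + 0.12.
BOUNDARY_SLOPE <- 0.58
BOUNDARY_INTERCEPT <- 0.12
## Aspect-ratio-5 variant: CF* >= 5.8 * PI* - 2.02.
BOUNDARY_AR5_SLOPE <- 5.8
BOUNDARY_AR5_INTERCEPT <- -2.02

habit_call <- function(label, rule, margin) {
  structure(list(label = label, rule_fired = rule, boundary_margin = margin),
            class = "habit_call")
}

#' @export
print.habit_call <- function(x, ...) {
  cat("habit:", x$label, " (rule:", x$rule_fired,
      ", margin:", signif(x$boundary_margin, 4), ")\n")
  invisible(x)
}

#' Classify habit from criteria fraction and Pearson index
#'
#' Applies the fixed decision boundary `CF >= 0.58 * PI + 0.12`
#' (asbestiform at or above the line). When `mixed_rules` is on, samples
#' below the line falling in the mixed-sample rectangles
#' (PI in \[0.3, 0.5\] and CF in \[0.2, 0.3\], or PI in \[0.4, 0.5\] and CF
#' in \[0.1, 0.2\]; all bounds inclusive) are flagged `undetermined` — the
#' region where a mostly non-asbestiform mixture can hide an asbestiform
#' component. Everything else is non-asbestiform.
#'
#' @param criteria_fraction fraction in \[0, 1\].
#' @param pearson_index correlation in \[-1, 1\].
#' @param mixed_rules apply the undetermined-zone rules (default `TRUE`).
#' @return a `habit_call`: `label` (asbestiform / non_asbestiform /
#'   undetermined), `rule_fired`, and `boundary_margin`
#'   (CF - 0.58 PI - 0.12).
#' @examples
#' classify_habit(0.459, 0.29)   # asbestiform
#' classify_habit(0.000, 0.77)   # non_asbestiform
#' classify_habit(0.25, 0.40)    # undetermined under the mixed-sample rules
#' @export
classify_habit <- function(criteria_fraction, pearson_index, mixed_rules = TRUE) {
  if (!is.finite(criteria_fraction) || criteria_fraction < 0 || criteria_fraction > 1)
    stop("criteria_fraction must be in [0, 1]")
  if (!is.finite(pearson_index) || abs(pearson_index) > 1)
    stop("pearson_index must be in [-1, 1]")
  margin <- criteria_fraction - (BOUNDARY_SLOPE * pearson_index + BOUNDARY_INTERCEPT)
  if (margin >= 0)
    return(habit_call("asbestiform", "boundary", margin))
  if (mixed_rules) {
    in_zone <-
      (pearson_index >= 0.3 && pearson_index <= 0.5 &&
         criteria_fraction >= 0.2 && criteria_fraction <= 0.3) ||
      (pearson_index >= 0.4 && pearson_index <= 0.5 &&
         criteria_fraction >= 0.1 && criteria_fraction <= 0.2)
    if (in_zone)
      return(habit_call("undetermined", "mixed_zone", margin))
  }
  habit_call("non_asbestiform", "boundary", margin)
}

#' @describeIn classify_habit Aspect-ratio >= 5 variant,
#'   `CF* >= 5.8 * PI* - 2.02`, with no undetermined zone.
#' @export
classify_habit_ar5 <- function(criteria_fraction, pearson_index) {
  if (!is.finite(criteria_fraction) || criteria_fraction < 0 || criteria_fraction > 1)
    stop("criteria_fraction must be in [0, 1]")
  if (!is.finite(pearson_index) || abs(pearson_index) > 1)
    stop("pearson_index must be in [-1, 1]")
  margin <- criteria_fraction -
    (BOUNDARY_AR5_SLOPE * pearson_index + BOUNDARY_AR5_INTERCEPT)
  habit_call(if (margin >= 0) "asbestiform" else "non_asbestiform",
             "boundary_ar5", margin)
}

#' Reference distribution for Mahalanobis classification
#'
#' Centroid and covariance of (length, width) over the main-window subset
#' of a reference population.
#'
#' @param particles particle data frame.
#' @param log_space work on log10 dimensions instead of raw micrometres.
#' @param filter counting-rule profile applied first.
#' @return list with `centroid` (length, width), `cov` (2x2), `n`.
#' @export
mahalanobis_reference <- function(particles, log_space = FALSE,
                                  filter = "main_emp") {
  sub <- emp_filter(particles, filter)
  if (nrow(sub) < 2) stop("reference needs at least 2 filtered particles")
  x <- cbind(length = sub$length_um, width = sub$width_um)
  if (log_space) x <- log10(x)
  list(centroid = colMeans(x), cov = stats::cov(x), n = nrow(sub))
}

pooled_cov <- function(ref_a, ref_b) {
  ## n - 1 weights, standard two-group pooling
  (ref_a$cov * (ref_a$n - 1) + ref_b$cov * (ref_b$n - 1)) /
    (ref_a$n + ref_b$n - 2)
}

#' Mahalanobis distance between a sample and a reference population
#'
#' Distance between the sample's (length, width) centroid and the
#' reference centroid under the pooled covariance of the two groups,
#' `D = sqrt((mu_X - mu_Y)' S^-1 (mu_X - mu_Y))`.
#'
#' @param sample particle data frame (>= 2 main-window particles).
#' @param reference a [mahalanobis_reference()].
#' @param pooled optional explicit pooled covariance matrix; by default the
#'   sample and reference covariances are pooled with n - 1 weights.
#' @param log_space match the space the reference was built in.
#' @param filter counting-rule profile applied to the sample.
#' @return the distance (dimensionless).
#' @export
emp_mahalanobis <- function(sample, reference, pooled = NULL,
                            log_space = FALSE, filter = "main_emp") {
  smp <- mahalanobis_reference(sample, log_space = log_space, filter = filter)
  S <- if (is.null(pooled)) pooled_cov(smp, reference) else pooled
  if (abs(det(S)) < .Machine$double.eps)
    stop("singular pooled covariance matrix")
  sqrt(mahalanobis(rbind(smp$centroid), reference$centroid, S))
}

#' Classify a sample by Mahalanobis proximity
#'
#' Assigns the label of the nearer of two reference distributions
#' (combined asbestiform and combined non-asbestiform particles); exactly
#' equal distances give `undetermined`.
#'
#' @param sample particle data frame.
#' @param ref_asb,ref_nonasb [mahalanobis_reference()] objects.
#' @param log_space,filter passed to [emp_mahalanobis()].
#' @return a `habit_call`; `boundary_margin` holds
#'   `d_nonasb - d_asb` (positive = closer to asbestiform).
#' @export
classify_mahalanobis <- function(sample, ref_asb, ref_nonasb,
                                 log_space = FALSE, filter = "main_emp") {
  d_a <- emp_mahalanobis(sample, ref_asb, log_space = log_space, filter = filter)
  d_n <- emp_mahalanobis(sample, ref_nonasb, log_space = log_space, filter = filter)
  lab <- if (d_a < d_n) "asbestiform" else if (d_n < d_a) "non_asbestiform"
  else "undetermined"
  out <- habit_call(lab, "mahalanobis", d_n - d_a)
  out$d_asb <- d_a; out$d_nonasb <- d_n
  out
}

#' Refit the linear decision boundary by a soft-margin separator
#'
#' Fits a maximum-margin linear separator (linear-kernel support vector
#' machine, penalty `C = 1000` by default) to labelled
#' (Pearson index, criteria fraction) points and reports it in the form
#' `CF >= slope * PI + intercept` with the asbestiform class above the
#' line. Refitting is opt-in; the fixed published boundary remains the
#' default classifier.
#'
#' @param pearson_index,criteria_fraction coordinates of the training points.
#' @param labels habit labels; anything equal to `"asbestiform"` is the
#'   positive class.
#' @param cost soft-margin penalty.
#' @return list with `slope`, `intercept`, `n_violations` (points on the
#'   wrong side of the fitted line) and `predicted` labels.
#' @export
fit_linear_boundary <- function(pearson_index, criteria_fraction, labels,
                                cost = 1000) {
  y <- factor(ifelse(labels == "asbestiform", "asbestiform", "non_asbestiform"),
              levels = c("asbestiform", "non_asbestiform"))
  if (nlevels(droplevels(y)) < 2)
    stop("need points from both classes")
  if (min(table(y)) < 2) stop("need at least 2 points per class")
  x <- cbind(pi = pearson_index, cf = criteria_fraction)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)   # decision = w . x - rho
  rho <- fit$rho
  if (abs(w["cf"]) < 1e-12) stop("degenerate separator (vertical boundary)")
  slope <- -w["pi"] / w["cf"]
  intercept <- rho / w["cf"]
  ## report with the asbestiform class above the line; orientation is set
  ## by which side the asbestiform training points fall on
  above <- criteria_fraction >= slope * pearson_index + intercept
  asb_above <- mean(above[y == "asbestiform"]) >= mean(above[y == "non_asbestiform"])
  predicted <- if (asb_above) ifelse(above, "asbestiform", "non_asbestiform")
  else ifelse(above, "non_asbestiform", "asbestiform")
  list(slope = unname(slope), intercept = unname(intercept),
       n_violations = sum(predicted != as.character(y)),
       predicted = predicted)
}

#' Classify every dataset in a particle table
#'
#' Groups a particle table by `dataset_id`, summarises each group and
#' applies the decision boundary (and optionally Mahalanobis proximity).
#'
#' @param particles particle data frame with a `dataset_id` column.
#' @param mixed_rules,ar5 passed to the boundary classifier.
#' @param params [dcc_params()] for the summaries.
#' @return data frame with one row per dataset: indices, habit call, rule
#'   and margin.
#' @export
classify_datasets <- function(particles, mixed_rules = TRUE, ar5 = FALSE,
                              params = dcc_params()) {
  stopifnot(is.data.frame(particles))
  if (is.null(particles$dataset_id)) particles$dataset_id <- "sample"
  ids <- unique(particles$dataset_id)
  rows <- lapply(ids, function(id) {
    s <- summarize_population(particles[particles$dataset_id == id, , drop = FALSE],
                              params = params, ar5 = ar5)
    call <- if (ar5) classify_habit_ar5(s$criteria_fraction, s$pearson_index)
    else classify_habit(s$criteria_fraction, s$pearson_index, mixed_rules)
    data.frame(dataset_id = id, n_particles = s$n_particles,
               criteria_fraction = s$criteria_fraction,
               pearson_index = s$pearson_index, mean_dcc = s$mean_dcc,
               habit_call = call$label, rule_fired = call$rule_fired,
               boundary_margin = call$boundary_margin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
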