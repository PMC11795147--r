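test_that("thickness follows the class-specific empirical rules", {
  # closed form at log10(W) = 0
  expect_equal(emp_thickness(1.0, "amphibole_asbestiform_or_mixed"),
               10^(-0.493), tolerance = 1e-12)
  expect_equal(emp_thickness(1.9, "other_nonserpentine"), 1.0)
  expect_equal(emp_thickness(0.5, "erionite"), 0.5)
  expect_equal(emp_thickness(1.1, "balangeroite"), 1.0)
  expect_equal(emp_thickness(3, "fibrous_talc"), 1.0)
  # vectorised over mixed classes
  expect_equal(emp_thickness(c(0.5, 1.9), c("erionite", "other_nonserpentine")),
               c(0.5, 1.0))
  expect_error(emp_thickness(1, "serpentine"), "undefined for serpentine")
  expect_error(emp_thickness(-1, "erionite"), "width")
  expect_error(emp_thickness(1, "quartz"), "unknown mineral_class")
})

test_that("amphibole thickness stays below width across the observed range", {
  w <- seq(0.05, 3, length.out = 400)
  th <- emp_thickness(w, "amphibole_asbestiform_or_mixed")
  expect_true(all(th < w))
  # the regression crosses Th = W only at 10^(-0.493/0.308), far below the
  # measurable width range
  cross <- 10^(-0.493 / 0.308)
  expect_lt(cross, 0.05)
  expect_gt(emp_thickness(cross * 0.5, "amphibole_asbestiform_or_mixed"),
            cross * 0.5)
})

test_that("surface area uses the serpentine and prism models correctly", {
  expect_equal(emp_surface_area(10, 1, "serpentine"), 10.5 * pi,
               tolerance = 1e-12)
  # thickness override hook: 2LW + 2L*Th + 2W*Th = 20 + 10 + 1
  expect_equal(emp_surface_area(10, 1, "other_nonserpentine", thickness = 0.5),
               31)
  expect_equal(emp_surface_area(11.4, 0.35, "amphibole_asbestiform_or_mixed"),
               11.633, tolerance = 1e-4)
  expect_error(emp_surface_area(-1, 1, "serpentine"), "length and width")
})

test_that("aerodynamic diameter matches Timbrell's relation and its bound", {
  expect_equal(emp_aerodynamic_diameter(1, 3, 1), 66 * (3 / 14)^2.2,
               tolerance = 1e-12)
  expect_equal(emp_aerodynamic_diameter(1, 3, 1), 2.225, tolerance = 1e-3)
  # strictly below the aspect-ratio supremum for any finite AR
  set.seed(1)
  w <- runif(200, 0.05, 3); ar <- runif(200, 1, 500); rho <- runif(200, 2, 4)
  ad <- emp_aerodynamic_diameter(w, ar, rho)
  expect_true(all(ad < 66 * w * 0.25^2.2 * sqrt(rho)))
  # increasing in width at fixed AR and density
  expect_true(all(diff(emp_aerodynamic_diameter(seq(0.1, 3, 0.1), 5, 3)) > 0))
  expect_error(emp_aerodynamic_diameter(1, 3, 0), "density")
})

test_that("criteria score and boundary behave as specified", {
  expect_equal(emp_criteria_score(10, 0.25), 2.694, tolerance = 1e-3)
  expect_equal(emp_criteria_score(10, 1.0), -0.81, tolerance = 1e-12)
  # boundary width at L = 10: 5.82 log10(W) = -0.81; inclusive boundary
  w0 <- 10^(-0.81 / 5.82)
  expect_equal(emp_criteria_score(10, w0), 0, tolerance = 1e-12)
  expect_true(is_criteria_particle(10, w0))
  expect_error(emp_criteria_score(0, 1), "length and width")
})

test_that("criteria sign agrees with brute-force evaluation on random pairs", {
  set.seed(42)
  L <- 10^runif(1e4, 0, 2); W <- 10^runif(1e4, -1.5, 0.7)
  brute <- (L^2.99 / W^5.82) >= 10^3.80  # corrected-ratio form of the rule
  expect_equal(is_criteria_particle(L, W), brute)
})

test_that("DCC is a probabilistic score with the right monotonicities", {
  expect_equal(emp_dcc(0, 0.3), 0)
  expect_equal(emp_dcc(13.47, 0.31), 0.0470, tolerance = 1e-3)
  set.seed(7)
  w <- runif(100, 0.05, 3)
  for (wi in w[1:5]) {
    sa <- seq(0, 100, length.out = 50)
    expect_true(all(diff(emp_dcc(sa, wi)) > 0))  # increasing in SA
  }
  vals <- emp_dcc(runif(1000, 0, 500), runif(1000, 0.05, 5))
  expect_true(all(vals >= 0 & vals <= 1))
  # strictly below 1 wherever the exponent is not astronomically large
  mod <- emp_dcc(runif(1000, 0, 60), runif(1000, 0.2, 5))
  expect_true(all(mod < 1))
  # vanishes for very wide particles at fixed surface area
  expect_lt(emp_dcc(100, 50), 1e-6)
  expect_error(emp_dcc(10, 0), "width")
})

test_that("dcc_params validates and carries the fitted defaults", {
  p <- dcc_params()
  expect_equal(unlist(p[c("A", "K", "B", "T", "C")]),
               c(A = 0.11, K = 1, B = 1000, T = 3, C = 1))
  expect_error(dcc_params(A = -1), "> 0")
})

test_that("particle_metrics wires all derived columns", {
  p <- make_particles(c(10, 10), c(1, 1),
                      mineral_class = c("serpentine",
                                        "amphibole_asbestiform_or_mixed"))
  m <- particle_metrics(p)
  expect_equal(m$surface_area[1], 10.5 * pi, tolerance = 1e-12)
  expect_true(is.na(m$thickness[1]))
  expect_equal(m$thickness[2], 10^(-0.493), tolerance = 1e-12)
  expect_equal(m$aspect_ratio, c(10, 10))
  expect_equal(m$dcc, emp_dcc(m$surface_area, m$width_um))
  empty <- particle_metrics(make_particles(numeric(0), numeric(0)))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("dcc", "criteria") %in% names(empty)))
})
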