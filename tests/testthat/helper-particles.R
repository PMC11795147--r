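# in-code fixture builders used across test files

make_particles <- function(length_um, width_um,
                           mineral_class = "amphibole_asbestiform_or_mixed",
                           density = 3.0, dataset_id = "test") {
  n <- length(length_um)
  data.frame(length_um = length_um, width_um = width_um,
             mineral_class = rep_len(mineral_class, n),
             density = rep_len(density, n),
             dataset_id = rep_len(dataset_id, n), stringsAsFactors = FALSE)
}

# DCC values of the 16 testing datasets (printed at 3 decimals), by habit
testing_dcc_asb <- c(0.027, 0.048, 0.040, 0.025, 0.057, 0.058, 0.044, 0.068)
testing_dcc_nonasb <- c(0.005, 0.001, 0.004, 0.002, 0.003, 0.002, 0.005, 0.005)

# pooled synthetic testing-set populations (built once per test run)
pooled_testing_pops <- local({
  cache <- NULL
  function(n = 2000, seed = 100) {
    if (!is.null(cache)) return(cache)
    specs <- default_population_specs(n = n, seed = seed)
    t5 <- emp_table("table5")
    testing <- t5$dataset[t5$group == "testing"]
    pops <- lapply(specs[testing], generate_population)
    habits <- vapply(specs[testing], `[[`, character(1), "habit")
    cache <<- list(
      pops = pops, habits = habits,
      asb = do.call(rbind, pops[habits == "asbestiform"]),
      nonasb = do.call(rbind, pops[habits == "non_asbestiform"]))
    cache
  }
})
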