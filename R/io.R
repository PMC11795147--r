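TABLE_FILES <- c(
  table4 = "table04_mineral_potency.csv",
  table5 = "table05_dataset_summaries.csv",
  table7 = "table07_dcc_potency.csv",
  table8 = "table08_dataset_indices.csv",
  table9 = "table09_habit_calls.csv",
  table11 = "table11_modeled_potency.csv",
  table12 = "table12_hc50.csv",
  table13 = "table13_rat_potency.csv")

#' Bundled reference tables
#'
#' Read-only tables shipped with the package, transcribed at printed
#' precision: `table4` per-mineral potency, biosolubility, width and
#' surface area; `table5` per-dataset dimensional summaries; `table7`
#' per-mineral average DCC and modelled potency; `table8` per-dataset
#' criteria fraction, Pearson index and DCC; `table9` a-priori and
#' a-posteriori habit; `table11` modelled per-dataset potency columns;
#' `table12` HC50 cytotoxicity; `table13` rat relative-potency modelling.
#'
#' @param id table identifier.
#' @return a data frame.
#' @examples
#' emp_table("table4")
#' @export
emp_table <- function(id = names(TABLE_FILES)) {
  id <- match.arg(id)
  path <- system.file("extdata", TABLE_FILES[[id]], package = "empdcc",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
}

#' Mineral configuration
#'
#' Editable mineral lookup: density (g/cm^3), default biosolubility
#' (years) and thickness-rule mineral class per mineral name. Densities
#' are standard literature values; small variations have minor effect on
#' aerodynamic diameter.
#'
#' @param path optional path to a user-supplied CSV with the same columns.
#' @return data frame with `mineral`, `density_g_cm3`, `biosolubility_yr`,
#'   `mineral_class`.
#' @export
mineral_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mineral_config.csv", package = "empdcc",
                        mustWork = TRUE)
  cfg <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("mineral", "density_g_cm3", "biosolubility_yr", "mineral_class")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("mineral config missing columns: ",
                         paste(miss, collapse = ", "))
  check_mineral_class(cfg$mineral_class)
  cfg
}

#' Read a particle table
#'
#' Reads a CSV or TSV particle table (delimiter sniffed from the header
#' line unless given). Required columns: `length_um`, `width_um`.
#' Optional: `mineral_class` (default `other_nonserpentine`), `mineral`
#' (used to fill class/density from [mineral_config()]), `density`,
#' `dataset_id`, `habit`. Rows with missing or non-positive dimensions are
#' dropped with a message naming their line numbers.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` to sniff `,` vs tab.
#' @param quiet suppress the rejected-row message.
#' @return a particle data frame (all datasets; split on `dataset_id`
#'   downstream as needed).
#' @export
read_particles <- function(path, sep = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c("length_um", "width_um"), names(raw))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  raw$length_um <- as.numeric(raw$length_um)
  raw$width_um <- as.numeric(raw$width_um)
  ok <- is.finite(raw$length_um) & raw$length_um > 0 &
    is.finite(raw$width_um) & raw$width_um > 0
  if (any(!ok) && !quiet)
    message("rejected ", sum(!ok), " malformed row(s) at line(s): ",
            paste(which(!ok) + 1L, collapse = ", "))
  out <- raw[ok, , drop = FALSE]
  cfg <- mineral_config()
  if (is.null(out$mineral_class)) {
    out$mineral_class <- if (!is.null(out$mineral)) {
      cls <- cfg$mineral_class[match(tolower(out$mineral), cfg$mineral)]
      ifelse(is.na(cls), "other_nonserpentine", cls)
    } else rep("other_nonserpentine", nrow(out))
  }
  unknown <- !(out$mineral_class %in% MINERAL_CLASSES)
  if (any(unknown)) {
    if (!quiet) message("unknown mineral_class in ", sum(unknown),
                        " row(s); defaulting to other_nonserpentine")
    out$mineral_class[unknown] <- "other_nonserpentine"
  }
  if (is.null(out$density)) {
    out$density <- if (!is.null(out$mineral)) {
      d <- cfg$density_g_cm3[match(tolower(out$mineral), cfg$mineral)]
      ifelse(is.na(d), 3.0, d)
    } else rep(3.0, nrow(out))
  }
  if (is.null(out$dataset_id)) out$dataset_id <- "sample"
  rownames(out) <- NULL
  out
}

#' Write an analysis report
#'
#' Serialises per-dataset summaries (and optional habit calls and potency
#' estimates, joined on `dataset_id`) as TSV or JSON. JSON output carries a
#' schema version and full-precision numbers.
#'
#' @param summaries data frame with a `dataset_id` column.
#' @param path output file.
#' @param calls,potencies optional data frames with `dataset_id`.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(summaries, path, calls = NULL, potencies = NULL,
                         format = c("tsv", "json")) {
  format <- match.arg(format)
  out <- summaries
  merge_on_id <- function(a, b) {
    if (is.null(b)) return(a)
    if (!all(b$dataset_id %in% c(a$dataset_id, character(0))) && nrow(a))
      stop("dataset_id mismatch between report components")
    merge(a, b[, setdiff(names(b), setdiff(names(a), "dataset_id")),
               drop = FALSE], by = "dataset_id", all.x = TRUE, sort = FALSE)
  }
  out <- merge_on_id(out, calls)
  out <- merge_on_id(out, potencies)
  if (format == "tsv") {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(schema = "empdcc-report/1", datasets = out),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Recompute the headline quantities from the bundled tables
#'
#' Drives every reference computation from the bundled fixtures: the
#' DCC-potency model over the mineral table, the optimal width, the
#' habit-group DCC comparison, the decision boundary over all datasets,
#' the EMPA potency column, the rat-potency column, and the regression
#' refits. Each entry reports the observed value, the tabulated value and
#' a pass flag at printed precision (one unit in the last printed digit
#' for model columns driven by rounded inputs).
#'
#' @return data frame with columns `check`, `observed`, `expected`, `pass`.
#' @export
run_paper_reproduction <- function() {
  t4 <- emp_table("table4"); t5 <- emp_table("table5")
  t7 <- emp_table("table7"); t8 <- emp_table("table8")
  t9 <- emp_table("table9"); t12 <- emp_table("table12")
  t13 <- emp_table("table13")
  res <- list()
  add <- function(check, observed, expected, tol) {
    res[[length(res) + 1]] <<- data.frame(
      check = check, observed = observed, expected = expected,
      pass = abs(observed - expected) <= tol)
  }
  ## DCC-based potency per mineral (rounded-input tolerance: 1 last-digit unit)
  mod7 <- potency_dcc(t7$avg_dcc, t4$biosolubility_yr)
  for (i in seq_len(nrow(t7))) {
    digits <- nchar(sub("^[^.]*\\.?", "", format(t7$rm_percent_modeled[i],
                                                 scientific = FALSE)))
    add(paste0("potency_dcc:", t7$mineral[i]), round(mod7[i], digits),
        t7$rm_percent_modeled[i], 10^(-digits) + 1e-9)
  }
  add("optimal_width", optimal_width(), 0.13, 0.005)
  ## habit-group DCC separation
  test <- t8[t8$group == "testing", ]
  a <- test$dcc[test$habit_apriori == "asbestiform"]
  b <- test$dcc[test$habit_apriori == "non-asbestiform"]
  tt <- group_ttest(a, b)
  add("dcc_mean_asb", round(tt$mean_a, 3), 0.046, 5e-4)
  add("dcc_mean_nonasb", round(tt$mean_b, 4), 0.0034, 5e-5)
  add("welch_t", round(tt$t_statistic, 2), 7.92, 5e-3)
  ## decision boundary over all 24 datasets
  calls <- vapply(seq_len(nrow(t8)), function(i)
    classify_habit(t8$criteria_fraction[i], t8$pearson_index[i])$label,
    character(1))
  expected <- ifelse(t9$habit_aposteriori == "asbestiform",
                     "asbestiform", "non_asbestiform")
  add("boundary_agreement", sum(calls == expected), nrow(t8), 0)
  ## EMPA potency spot values
  add("potency_empa:EasternNY",
      round(potency_empa(100 * t5$empa_fraction[t5$dataset == "Eastern New York"]), 3),
      0.701, 5e-4)
  add("potency_empa:Metsovo",
      round(potency_empa(100 * t5$empa_fraction[t5$dataset == "Metsovo Greece"]), 3),
      0.325, 5e-4)
  ## rat potency column, chained from each sample's average DCC and
  ## biosolubility through the human-potency model
  rm13 <- potency_dcc(t13$avg_dcc, t13$biosolubility_yr)
  mod13 <- rat_relative_potency(rm13)
  for (i in seq_len(nrow(t13))) {
    add(paste0("potency_dcc:", t13$mineral[i]), round(rm13[i], 3),
        t13$rm_percent_modeled[i], 5e-4 + 1e-9)
    add(paste0("rat_potency:", t13$mineral[i]), round(mod13[i], 2),
        t13$relative_potency_modeled[i], 5e-3 + 1e-9)
  }
  ## regression refits
  f14 <- refit_regression(test$dcc, data.frame(cf = test$criteria_fraction))
  add("refit_dcc_cf_slope", unname(f14$coefficients["cf"]), 0.06, 0.01)
  add("refit_dcc_cf_r", f14$r, 0.96, 0.02)
  hc <- merge(t12, t8[, c("dataset", "dcc")], by = "dataset")
  f17 <- refit_regression(hc$hc50_fibers_1e9_ml, data.frame(dcc = hc$dcc),
                          log_y = TRUE)
  add("refit_hc50_slope", unname(f17$coefficients["dcc"]), 17.12, 0.5)
  add("refit_hc50_intercept", unname(f17$coefficients["(Intercept)"]),
      -1.06, 0.05)
  do.call(rbind, res)
}
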