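#' @title Pipeline orchestration and reporting
#' @description End-to-end runs — unit costing (when a ledger is supplied),
#'   micro-costing, the log-linear cost model with trimming, and predicted
#'   per-complication costs — with CSV/JSON outputs carrying the run seed
#'   and configuration hash, plus a human-readable markdown report. The R
#'   functions are the primary interface; a thin command-line wrapper over
#'   [run_pipeline()] ships in \code{inst/cli/obcost.R}.
#' @name cli_report
NULL

# Polynomial rolling hash over the deparsed config; fingerprints a run.
# Output location is excluded: two runs of the same analysis share a hash.
config_hash <- function(config) {
  config$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default run configuration
#'
#' @param simulate Generate inputs synthetically instead of reading files.
#' @param seed Integer seed for every source of randomness.
#' @param cohort_size Synthetic cohort size (when simulating).
#' @param sigma Log-scale noise SD of the synthetic generator.
#' @param input_dir Directory holding \code{patients.csv},
#'   \code{utilization.csv}, \code{prices.csv} and, optionally, the four
#'   ledger files (when not simulating).
#' @param out_dir Output directory.
#' @param exchange_rate MMK per USD.
#' @param discount_rate Discount rate for capital annualization.
#' @param p_enter,p_remove,sdr_threshold,reference Model settings, see
#'   [cost_model_spec()].
#' @param fixed_model Optional list with \code{coefficients} (named),
#'   \code{smearing} and optionally \code{reference}: skip fitting and
#'   predict from these externally supplied coefficients.
#' @param predict_age Age at which per-category costs are predicted;
#'   \code{NULL} for the cohort mean age.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(simulate = TRUE, seed = 1L, cohort_size = 91,
                       sigma = 0.1,
                       input_dir = NULL, out_dir = tempfile("obcost_run_"),
                       exchange_rate = 1199.07, discount_rate = 0.03,
                       p_enter = 0.05, p_remove = 0.10, sdr_threshold = 2,
                       reference = NULL, fixed_model = NULL,
                       predict_age = NULL) {
  structure(list(simulate = isTRUE(simulate), seed = as.integer(seed),
                 cohort_size = as.integer(cohort_size), sigma = sigma,
                 input_dir = input_dir,
                 out_dir = out_dir, exchange_rate = exchange_rate,
                 discount_rate = discount_rate, p_enter = p_enter,
                 p_remove = p_remove, sdr_threshold = sdr_threshold,
                 reference = reference, fixed_model = fixed_model,
                 predict_age = predict_age),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file does not exist: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(vals$fixed_model) && !is.null(vals$fixed_model$coefficients))
    vals$fixed_model$coefficients <- unlist(vals$fixed_model$coefficients)
  do.call(run_config, vals)
}

#' Run the full costing pipeline
#'
#' Loads or simulates the inputs, computes service unit costs from the
#' ledger (when one is available), prices every patient bottom-up,
#' summarizes the cohort, fits the trimmed log-linear cost model (or uses a
#' fixed one), predicts per-complication costs, and writes
#' \code{treatment_costs.csv}, \code{summary.csv}, \code{shares.csv},
#' \code{unit_costs.csv}, \code{model.json}, \code{predictions.csv},
#' \code{report.md} and \code{run_summary.json} to the output directory.
#' Every CSV carries a metadata header with the seed and a hash of the
#' configuration, and reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @return List of class \code{pipeline_run} with all intermediate objects
#'   and output \code{paths}, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = config$seed, config = config_hash(config))

  if (config$simulate) {
    params <- cohort_params(n = config$cohort_size, sigma = config$sigma)
    sim <- simulate_dataset(params, seed = config$seed,
                            exchange_rate = config$exchange_rate)
    patients <- sim$patients; utilization <- sim$utilization
    prices <- sim$prices; ledger <- sim$ledger
  } else {
    if (is.null(config$input_dir))
      stop("input stage: input_dir is required when simulate = FALSE",
           call. = FALSE)
    patients <- read_patients(file.path(config$input_dir, "patients.csv"))
    utilization <- read_utilization(file.path(config$input_dir, "utilization.csv"))
    prices <- read_prices(file.path(config$input_dir, "prices.csv"))
    ledger_files <- file.path(config$input_dir,
                              c("cost_centers.csv", "capital_assets.csv",
                                "allocation_bases.csv", "outputs.csv"))
    ledger <- if (all(file.exists(ledger_files)))
      do.call(read_ledger, as.list(ledger_files)) else NULL
  }

  paths <- character()
  unit_costs <- NULL
  if (!is.null(ledger)) {
    unit_costs <- compute_unit_costs(ledger, rate = config$discount_rate)
    paths["unit_costs"] <- file.path(config$out_dir, "unit_costs.csv")
    write_pipeline_csv(unit_costs, paths["unit_costs"], meta)
  }

  costs <- compute_treatment_costs(patients, utilization, prices)
  summary <- cost_summary(costs, patients)
  shares <- if (nrow(costs)) cost_shares(summary) else NULL
  paths["treatment_costs"] <- file.path(config$out_dir, "treatment_costs.csv")
  write_pipeline_csv(as.data.frame(costs), paths["treatment_costs"], meta)
  paths["summary"] <- file.path(config$out_dir, "summary.csv")
  write_pipeline_csv(as.data.frame(summary), paths["summary"], meta)
  if (!is.null(shares)) {
    paths["shares"] <- file.path(config$out_dir, "shares.csv")
    write_pipeline_csv(shares, paths["shares"], meta)
  }

  spec <- cost_model_spec(p_enter = config$p_enter, p_remove = config$p_remove,
                          sdr_threshold = config$sdr_threshold,
                          reference = config$reference,
                          exchange_rate = config$exchange_rate)
  model <- NULL
  if (!is.null(config$fixed_model)) {
    fm <- config$fixed_model
    fit <- fixed_cost_model(fm$coefficients, smearing = fm$smearing,
                            reference = if (is.null(fm$reference)) "aph"
                                        else fm$reference)
  } else if (nrow(patients) > 0) {
    model <- trim_and_refit(patients, costs, spec)
    fit <- model$trimmed
  } else {
    fit <- NULL
  }

  predictions <- NULL
  if (!is.null(fit)) {
    age <- if (!is.null(config$predict_age)) config$predict_age
           else if (nrow(patients)) mean(patients$age) else NA_real_
    cats <- unique(c(fit$reference,
                     intersect(fit$selected, complication_levels())))
    predictions <- data.frame(
      category = cats,
      predicted_usd = unname(predict_category_cost(
        fit, cats, age = age, exchange_rate = config$exchange_rate)),
      age = age, smearing = fit$smearing, stringsAsFactors = FALSE)
    paths["predictions"] <- file.path(config$out_dir, "predictions.csv")
    write_pipeline_csv(predictions, paths["predictions"], meta)

    model_json <- list(
      coefficients = fit$coefficients,
      r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
      n = fit$n, smearing = fit$smearing, reference = fit$reference,
      dropped = if (!is.null(model)) model$dropped else character(),
      diagnostics = if (!is.null(model)) list(
        durbin_watson = model$diagnostics$durbin_watson,
        criteria = as.list(model$diagnostics$criteria),
        tolerance = as.list(model$diagnostics$collinearity$tolerance),
        vif = as.list(model$diagnostics$collinearity$vif),
        condition_index_max = max(model$diagnostics$collinearity$condition_indices),
        cooks_max = max(model$diagnostics$cases$cooks)) else NULL,
      seed = config$seed, config = meta$config)
    paths["model"] <- file.path(config$out_dir, "model.json")
    jsonlite::write_json(model_json, paths["model"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }

  run <- structure(list(config = config, patients = patients,
                        utilization = utilization, prices = prices,
                        ledger = ledger, unit_costs = unit_costs,
                        costs = costs, summary = summary, shares = shares,
                        model = model, fit = fit, predictions = predictions,
                        paths = paths, meta = meta),
                   class = "pipeline_run")

  paths["report"] <- file.path(config$out_dir, "report.md")
  writeLines(render_report(run), paths["report"])
  run$paths <- paths

  run_summary <- list(seed = config$seed, config = meta$config,
                      n_patients = nrow(patients),
                      total_cost = if (nrow(costs)) sum(costs$total) else 0,
                      currency = attr(costs, "currency"),
                      outputs = as.list(paths))
  paths["run_summary"] <- file.path(config$out_dir, "run_summary.json")
  jsonlite::write_json(run_summary, paths["run_summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  run$paths <- paths
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d patients, outputs in %s\n",
              nrow(x$patients), x$config$out_dir))
  invisible(x)
}

fmt_table <- function(df, digits = 2) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) formatC(round(col, digits), format = "f",
                                 digits = digits) else as.character(col))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render a markdown run report
#'
#' Produces the four conventional report tables — cohort demographics, cost
#' summary by category, fitted model coefficients, and per-complication
#' predicted costs — plus the category cost shares and a diagnostics
#' pass/fail panel.
#'
#' @param run A [run_pipeline()] result.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  p <- run$patients
  lines <- c("# Obstetric complication costing report", "",
             sprintf("Seed %d, config %s.", run$config$seed, run$meta$config), "")
  labels <- complication_labels()

  lines <- c(lines, "## Cohort demographics", "")
  if (nrow(p) == 0) {
    lines <- c(lines, "No cases.", "")
  } else {
    demo <- data.frame(
      variable = c("n", "Age mean (SD)", "Age < 30", "Age >= 30", "Rural",
                   "Urban", "ANC received", "Length of stay mean (median)",
                   paste0(labels[intersect(complication_levels(),
                                           unique(p$complication))])),
      value = c(nrow(p),
                sprintf("%.2f (%.2f)", mean(p$age), stats::sd(p$age)),
                sprintf("%d (%.1f%%)", sum(p$age < 30), 100 * mean(p$age < 30)),
                sprintf("%d (%.1f%%)", sum(p$age >= 30), 100 * mean(p$age >= 30)),
                sprintf("%d (%.1f%%)", sum(p$location == "rural"),
                        100 * mean(p$location == "rural")),
                sprintf("%d (%.1f%%)", sum(p$location == "urban"),
                        100 * mean(p$location == "urban")),
                sprintf("%d (%.1f%%)", sum(p$anc_received),
                        100 * mean(p$anc_received)),
                sprintf("%.2f (%g)", mean(p$length_of_stay),
                        stats::median(p$length_of_stay)),
                vapply(intersect(complication_levels(), unique(p$complication)),
                       function(cat) sprintf("%d (%.1f%%)",
                                             sum(p$complication == cat),
                                             100 * mean(p$complication == cat)),
                       character(1))),
      stringsAsFactors = FALSE)
    lines <- c(lines, fmt_table(demo), "")
  }

  lines <- c(lines, "## Treatment cost by category", "")
  if (is.null(run$summary) || nrow(run$summary) == 0) {
    lines <- c(lines, "No cases.", "")
  } else {
    s <- run$summary[run$summary$stratum %in% c("overall", "category"),
                     c("category", "n", "total_mean", "total_sd",
                       "total_median", "total_total")]
    names(s) <- c("category", "n", "mean", "sd", "median", "total")
    lines <- c(lines, fmt_table(s), "",
               sprintf("Currency: %s.", attr(run$costs, "currency")), "")
  }

  lines <- c(lines, "## Cost shares", "")
  if (is.null(run$shares)) {
    lines <- c(lines, "No cases.", "")
  } else {
    lines <- c(lines, fmt_table(run$shares),
               sprintf("Shares sum to %.1f%%.", sum(run$shares$share)), "")
  }

  lines <- c(lines, "## Fitted cost model", "")
  if (is.null(run$fit)) {
    lines <- c(lines, "No model (no cases).", "")
  } else {
    lines <- c(lines, fmt_table(run$fit$coefficients, digits = 3), "")
    if (!is.null(run$fit$r_squared))
      lines <- c(lines, sprintf(
        "n = %d; R-squared %.3f (adjusted %.3f); smearing factor %.4f; reference %s.",
        run$fit$n, run$fit$r_squared, run$fit$adj_r_squared,
        run$fit$smearing, run$fit$reference), "")
    if (!is.null(run$model)) {
      d <- run$model$diagnostics
      panel <- data.frame(
        check = c("Durbin-Watson in [1.5, 2.5]", "Condition index <= 30",
                  "Tolerance > 0.1", "VIF < 10", "Cook's distance < 1",
                  "No |SDR| outliers"),
        value = c(sprintf("%.3f", d$durbin_watson),
                  sprintf("%.3f", max(d$collinearity$condition_indices)),
                  if (length(d$collinearity$tolerance) &&
                      !all(is.na(d$collinearity$tolerance)))
                    sprintf("%.3f", min(d$collinearity$tolerance, na.rm = TRUE))
                  else "n/a",
                  if (length(d$collinearity$vif) &&
                      !all(is.na(d$collinearity$vif)))
                    sprintf("%.3f", max(d$collinearity$vif, na.rm = TRUE))
                  else "n/a",
                  sprintf("%.3f", max(d$cases$cooks[!d$cases$undefined])),
                  sprintf("%d flagged", sum(d$cases$outlier))),
        status = ifelse(d$criteria, "pass", "FAIL"),
        stringsAsFactors = FALSE)
      lines <- c(lines, "### Diagnostics", "", fmt_table(panel), "",
                 sprintf("Cases dropped by trimming: %s.",
                         if (length(run$model$dropped))
                           paste(run$model$dropped, collapse = ", ")
                         else "none"), "")
    }
  }

  lines <- c(lines, "## Predicted cost by complication", "")
  if (is.null(run$predictions)) {
    lines <- c(lines, "No predictions (no model).", "")
  } else {
    pr <- run$predictions
    pr$category <- unname(labels[pr$category])
    lines <- c(lines, fmt_table(pr[c("category", "predicted_usd")]), "",
               sprintf("Predicted at age %.2f with smearing factor %.4f.",
                       run$predictions$age[1], run$predictions$smearing[1]), "")
  }
  lines
}
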