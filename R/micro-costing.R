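#' @title Bottom-up patient treatment costing
#' @description Per-patient direct medical cost from itemized utilization
#'   (quantity times unit cost, summed within the four components: drug,
#'   laboratory, routine service, operation) and cohort summaries by
#'   complication category and age group.
#' @name micro_costing
NULL

cost_components <- function() c("drug", "laboratory", "routine", "operation")

#' Per-patient treatment cost from itemized utilization
#'
#' Prices every utilization item of one patient and sums quantities times
#' unit costs within each of the four cost components. The total is exactly
#' the sum of the components, in the currency of the price table.
#'
#' @param patient_id Identifier of the patient (used in error messages).
#' @param utilization Data frame of this patient's items: \code{item},
#'   \code{quantity}.
#' @param prices A [price_table()] resolving every item.
#' @return One-row data frame with \code{patient_id}, \code{drug_cost},
#'   \code{laboratory_cost}, \code{routine_cost}, \code{operation_cost},
#'   \code{total}.
#' @export
patient_cost <- function(patient_id, utilization, prices) {
  stopifnot(inherits(prices, "price_table"))
  comp <- stats::setNames(numeric(4), cost_components())
  if (nrow(utilization)) {
    idx <- match(utilization$item, prices$item)
    if (anyNA(idx))
      stop("unpriced item(s) for patient ", patient_id, ": ",
           paste(unique(utilization$item[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    amount <- utilization$quantity * prices$unit_cost[idx]
    sums <- tapply(amount, factor(prices$kind[idx], levels = cost_components()),
                   sum, default = 0)
    comp[names(sums)] <- sums
  }
  data.frame(patient_id = as.character(patient_id),
             drug_cost = comp[["drug"]], laboratory_cost = comp[["laboratory"]],
             routine_cost = comp[["routine"]], operation_cost = comp[["operation"]],
             total = sum(comp), stringsAsFactors = FALSE)
}

#' Treatment costs for a whole cohort
#'
#' @param patients Validated cohort data frame (see [read_patients()]).
#' @param utilization Long-format utilization data frame for the cohort.
#' @param prices A [price_table()].
#' @return Data frame of class \code{treatment_costs}, one row per patient in
#'   cohort order, with the four component costs and \code{total}; currency
#'   attached as attribute \code{currency}.
#' @export
compute_treatment_costs <- function(patients, utilization, prices) {
  utilization <- validate_utilization(utilization)
  stray <- setdiff(unique(utilization$patient_id), patients$patient_id)
  if (length(stray))
    stop("utilization for unknown patient(s): ",
         paste(stray, collapse = ", "), call. = FALSE)
  rows <- lapply(patients$patient_id, function(pid) {
    patient_cost(pid, utilization[utilization$patient_id == pid, , drop = FALSE],
                 prices)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(patient_id = character(), drug_cost = numeric(),
                      laboratory_cost = numeric(), routine_cost = numeric(),
                      operation_cost = numeric(), total = numeric(),
                      stringsAsFactors = FALSE)
  attr(out, "currency") <- attr(prices, "currency")
  class(out) <- c("treatment_costs", "data.frame")
  out
}

sample_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

stratum_stats <- function(costs) {
  comp_cols <- c("drug_cost", "laboratory_cost", "routine_cost",
                 "operation_cost", "total")
  stats_one <- function(col) {
    x <- costs[[col]]
    c(mean = if (length(x)) mean(x) else 0,
      sd = sample_sd(x),
      median = if (length(x)) stats::median(x) else 0,
      total = sum(x))
  }
  vals <- unlist(lapply(comp_cols, stats_one))
  names(vals) <- as.vector(outer(c("mean", "sd", "median", "total"),
                                 sub("_cost$", "", comp_cols),
                                 function(s, c) paste(c, s, sep = "_")))
  c(n = nrow(costs), vals)
}

#' Cohort cost summary by complication category and age group
#'
#' Summarizes per-patient treatment costs the way cost-of-illness tables are
#' reported: for the overall cohort, per complication category, per age group
#' (below 30 versus 30 and over), and per category-by-age-group cell. For
#' each stratum it reports n and the mean, sample standard deviation (n-1
#' denominator, reported as 0 for singleton strata), median and total of the
#' patient totals and of each of the four components.
#'
#' @param costs A \code{treatment_costs} data frame.
#' @param patients The matching cohort data frame (one cost row per patient).
#' @param age_break Age group boundary in years; groups are
#'   \code{age < age_break} and \code{age >= age_break}.
#' @return Data frame of class \code{cost_summary}: columns \code{stratum}
#'   (\code{overall}, \code{category}, \code{age_group} or
#'   \code{category_age}), \code{category}, \code{age_group}, \code{n} and
#'   the per-component statistics; currency carried over as an attribute.
#' @export
cost_summary <- function(costs, patients, age_break = 30) {
  stopifnot(nrow(costs) == nrow(patients))
  if (nrow(costs) == 0L) {
    out <- data.frame(stratum = character(), category = character(),
                      age_group = character())
    class(out) <- c("cost_summary", "data.frame")
    return(out)
  }
  costs <- costs[match(patients$patient_id, costs$patient_id), , drop = FALSE]
  grp <- ifelse(patients$age < age_break,
                paste0("<", age_break), paste0(">=", age_break))
  cats <- intersect(complication_levels(), unique(patients$complication))
  rows <- list()
  add <- function(stratum, category, age_group, idx) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stratum = stratum, category = category, age_group = age_group,
      t(stratum_stats(costs[idx, , drop = FALSE])),
      stringsAsFactors = FALSE)
  }
  add("overall", "all", "all", seq_len(nrow(costs)))
  for (g in unique(c(paste0("<", age_break), paste0(">=", age_break))))
    add("age_group", "all", g, which(grp == g))
  for (cat in cats) {
    add("category", cat, "all", which(patients$complication == cat))
    for (g in c(paste0("<", age_break), paste0(">=", age_break)))
      add("category_age", cat, g, which(patients$complication == cat & grp == g))
  }
  out <- do.call(rbind, rows)
  attr(out, "currency") <- attr(costs, "currency")
  class(out) <- c("cost_summary", "data.frame")
  out
}

#' Category shares of the total treatment cost
#'
#' @param summary A [cost_summary()] result with a positive overall total.
#' @return Data frame with \code{category}, \code{total} and \code{share}
#'   (percent of the overall total, rounded to 2 decimals; the unrounded
#'   shares sum to exactly 100).
#' @export
cost_shares <- function(summary) {
  stopifnot(inherits(summary, "cost_summary"))
  overall <- summary$total_total[summary$stratum == "overall"]
  if (!length(overall) || overall <= 0)
    stop("overall total must be positive to compute shares", call. = FALSE)
  cat_rows <- summary[summary$stratum == "category", , drop = FALSE]
  data.frame(category = cat_rows$category,
             total = cat_rows$total_total,
             share = round(100 * cat_rows$total_total / overall, 2),
             stringsAsFactors = FALSE)
}

#' Convert treatment costs to another currency
#'
#' @param costs A \code{treatment_costs} data frame.
#' @param to Target currency code.
#' @param rate Exchange rate in MMK per USD.
#' @return The costs with all money columns converted.
#' @export
convert_costs <- function(costs, to, rate = 1199.07) {
  stopifnot(inherits(costs, "treatment_costs"))
  from <- attr(costs, "currency")
  money_cols <- c("drug_cost", "laboratory_cost", "routine_cost",
                  "operation_cost", "total")
  for (col in money_cols) costs[[col]] <- convert_currency(costs[[col]], from, to, rate)
  attr(costs, "currency") <- match.arg(to, c("MMK", "USD"))
  costs
}
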