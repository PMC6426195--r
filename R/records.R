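#' @title Patient records, price tables and delimited-text I/O
#' @description Domain types and validated readers/writers shared by all
#'   pipeline stages. Patient cohorts are plain data frames (one row per
#'   hospitalized case); itemized utilization is a long-format data frame
#'   joined on \code{patient_id}; prices are a \code{price_table}.
#' @name records
NULL

#' Canonical complication categories
#'
#' The seven obstetric complication categories handled by the pipeline, as
#' lowercase tokens. The display names used in reports are available through
#' \code{complication_labels()}.
#'
#' @return Character vector of the seven canonical category tokens, in the
#'   conventional reporting order.
#' @export
complication_levels <- function() {
  c("incomplete_abortion", "pid", "pih", "aph", "pph",
    "prolonged_labor", "septicemia")
}

#' @rdname complication_levels
#' @return \code{complication_labels()}: named character vector mapping each
#'   token to its human-readable name.
#' @export
complication_labels <- function() {
  c(incomplete_abortion = "Incomplete abortion",
    pid                 = "Pelvic inflammatory disease (PID)",
    pih                 = "Pregnancy-induced hypertension (PIH)",
    aph                 = "Ante-partum hemorrhage (APH)",
    pph                 = "Post-partum hemorrhage (PPH)",
    prolonged_labor     = "Prolonged labor",
    septicemia          = "Septicemia")
}

#' Currency conversion at a fixed exchange rate
#'
#' Converts money amounts between Myanmar kyat (MMK) and US dollars (USD)
#' using a fixed exchange rate expressed as MMK per USD. No rounding is
#' applied; display rounding is the caller's concern. Conversion is exact up
#' to floating point, so a round trip MMK -> USD -> MMK recovers the input to
#' better than 1 part in 1e9.
#'
#' @param amount Numeric vector of non-negative money amounts.
#' @param from,to Currency codes, \code{"MMK"} or \code{"USD"}.
#' @param rate Exchange rate in MMK per USD; must be positive. The default is
#'   the 2015 fiscal-year average for Myanmar.
#' @return Numeric vector of converted amounts.
#' @examples
#' convert_currency(1199.07, "MMK", "USD")  # 1
#' @export
convert_currency <- function(amount, from, to, rate = 1199.07) {
  from <- match.arg(from, c("MMK", "USD"))
  to <- match.arg(to, c("MMK", "USD"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0)
    stop("exchange rate must be a single positive number", call. = FALSE)
  if (from == to) return(amount)
  if (from == "MMK") amount / rate else amount * rate
}

#' Round half away from zero
#'
#' Display rounding of money amounts: exact halves round up (2.015 to 2
#' decimals is 2.02), the convention of printed cost tables, unlike base
#' \code{round()}'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Construct a price table
#'
#' A \code{price_table} maps item names to unit costs, each tagged with a
#' currency and a cost-component kind (\code{drug}, \code{laboratory},
#' \code{routine}, \code{operation}). All items in one table share a currency.
#'
#' @param item Character vector of unique item names.
#' @param unit_cost Numeric vector of non-negative unit costs.
#' @param kind Character vector of component kinds.
#' @param currency Single currency code for the whole table.
#' @return A data frame of class \code{price_table} with columns \code{item},
#'   \code{unit_cost}, \code{kind} and a \code{currency} attribute.
#' @seealso [default_price_table()] for the bundled service-price fixture.
#' @export
price_table <- function(item, unit_cost, kind, currency = "USD") {
  currency <- match.arg(currency, c("MMK", "USD"))
  kind <- match.arg(kind, c("drug", "laboratory", "routine", "operation"),
                    several.ok = TRUE)
  if (length(kind) == 1L) kind <- rep(kind, length(item))
  stopifnot(length(item) == length(unit_cost), length(kind) == length(item))
  if (anyDuplicated(item))
    stop("duplicate item names in price table: ",
         paste(unique(item[duplicated(item)]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(unit_cost)) || any(unit_cost < 0))
    stop("unit costs must be finite and non-negative", call. = FALSE)
  out <- data.frame(item = as.character(item), unit_cost = as.numeric(unit_cost),
                    kind = as.character(kind), stringsAsFactors = FALSE)
  attr(out, "currency") <- currency
  class(out) <- c("price_table", "data.frame")
  out
}

#' Convert all prices in a table to another currency
#'
#' @param prices A \code{price_table}.
#' @param to Target currency code.
#' @param rate Exchange rate in MMK per USD.
#' @return The table with converted unit costs and updated currency attribute.
#' @export
convert_prices <- function(prices, to, rate = 1199.07) {
  stopifnot(inherits(prices, "price_table"))
  from <- attr(prices, "currency")
  prices$unit_cost <- convert_currency(prices$unit_cost, from, to, rate)
  attr(prices, "currency") <- match.arg(to, c("MMK", "USD"))
  prices
}

#' @export
print.price_table <- function(x, ...) {
  cat(sprintf("Price table: %d items, currency %s\n", nrow(x), attr(x, "currency")))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... and %d more items\n", nrow(x) - 10L))
  invisible(x)
}

patient_columns <- function() {
  c("patient_id", "admission_order", "age", "location", "anc_received",
    "length_of_stay", "complication")
}

#' Validate a cohort of patient records
#'
#' Checks the patient data frame against the schema invariants: unique ids,
#' integer ages within bounds, location in \{rural, urban\}, logical ANC flag,
#' length of stay of at least one day, and complication labels drawn from the
#' seven canonical categories. Errors carry row numbers so that offending
#' source lines can be located.
#'
#' @param patients Data frame with columns \code{patient_id},
#'   \code{admission_order}, \code{age}, \code{location}, \code{anc_received},
#'   \code{length_of_stay}, \code{complication}.
#' @param age_bounds Length-2 numeric vector of admissible ages in years.
#' @return The validated data frame, invisibly coerced to canonical column
#'   types, with \code{admission_order} filled from row order when absent.
#' @export
validate_patients <- function(patients, age_bounds = c(10, 60)) {
  missing_cols <- setdiff(setdiff(patient_columns(), "admission_order"),
                          names(patients))
  if (length(missing_cols))
    stop("patient file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n <- nrow(patients)
  if (is.null(patients$admission_order))
    patients$admission_order <- seq_len(n)
  if (n == 0L) {
    patients <- patients[patient_columns()]
    return(invisible(patients))
  }
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id values", call. = FALSE)

  age <- suppressWarnings(as.numeric(patients$age))
  los <- suppressWarnings(as.numeric(patients$length_of_stay))
  bad <- which(is.na(age) | is.na(los))
  if (length(bad))
    stop("non-numeric age or length_of_stay in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out_of_bounds <- which(age < age_bounds[1] | age > age_bounds[2])
  if (length(out_of_bounds))
    stop(sprintf("age outside [%g, %g] in row(s): %s", age_bounds[1],
                 age_bounds[2], paste(out_of_bounds, collapse = ", ")),
         call. = FALSE)
  if (any(los < 1))
    stop("length_of_stay must be >= 1 day; offending row(s): ",
         paste(which(los < 1), collapse = ", "), call. = FALSE)

  comp <- as.character(patients$complication)
  unknown <- setdiff(unique(comp), complication_levels())
  if (length(unknown))
    stop("unknown complication label(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(complication_levels(), collapse = ", "),
         call. = FALSE)
  loc <- as.character(patients$location)
  if (!all(loc %in% c("rural", "urban")))
    stop("location must be 'rural' or 'urban'", call. = FALSE)

  patients$age <- as.integer(round(age))
  patients$length_of_stay <- as.integer(round(los))
  patients$location <- loc
  patients$anc_received <- as.logical(patients$anc_received)
  if (anyNA(patients$anc_received))
    stop("anc_received must be logical (TRUE/FALSE)", call. = FALSE)
  patients$admission_order <- as.integer(patients$admission_order)
  invisible(patients[patient_columns()])
}

#' Validate long-format utilization records
#'
#' @param utilization Data frame with columns \code{patient_id}, \code{item},
#'   \code{quantity}.
#' @return The validated data frame, invisibly.
#' @export
validate_utilization <- function(utilization) {
  needed <- c("patient_id", "item", "quantity")
  missing_cols <- setdiff(needed, names(utilization))
  if (length(missing_cols))
    stop("utilization file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  q <- suppressWarnings(as.numeric(utilization$quantity))
  if (anyNA(q) && nrow(utilization) > 0)
    stop("non-numeric quantity in row(s): ",
         paste(which(is.na(q)), collapse = ", "), call. = FALSE)
  if (any(q < 0))
    stop("negative quantity in row(s): ",
         paste(which(q < 0), collapse = ", "), call. = FALSE)
  utilization$quantity <- q
  utilization$patient_id <- as.character(utilization$patient_id)
  utilization$item <- as.character(utilization$item)
  invisible(utilization[needed])
}

# CSV plumbing: all pipeline files are UTF-8 comma-separated with one header
# row; lines starting with '#' hold run metadata (seed, config hash) and are
# skipped on read.
read_pipeline_csv <- function(path, required = character()) {
  if (!file.exists(path))
    stop("input file does not exist: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(basename(path), " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

write_pipeline_csv <- function(df, path, metadata = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(metadata))
    writeLines(paste0("# ", names(metadata), ": ", unlist(metadata)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read and write patient cohort files
#'
#' \code{read_patients()} reads a comma-separated patient file, validates it
#' and returns the cohort data frame; \code{write_patients()} writes one,
#' optionally with a metadata header of \code{# key: value} comment lines.
#' When the file lacks an \code{admission_order} column it is assigned from
#' row order (the residual-ordering used by the Durbin-Watson statistic).
#'
#' @param path File path.
#' @param age_bounds Passed to [validate_patients()].
#' @param patients A validated cohort data frame.
#' @param metadata Named list written as comment lines before the header.
#' @return \code{read_patients()}: the validated cohort data frame.
#' @export
read_patients <- function(path, age_bounds = c(10, 60)) {
  df <- read_pipeline_csv(path, setdiff(patient_columns(), "admission_order"))
  out <- validate_patients(df, age_bounds = age_bounds)
  out
}

#' @rdname read_patients
#' @export
write_patients <- function(patients, path, metadata = NULL) {
  write_pipeline_csv(as.data.frame(patients)[patient_columns()], path, metadata)
}

#' Read and write long-format utilization files
#'
#' @inheritParams read_patients
#' @param utilization A validated utilization data frame.
#' @return \code{read_utilization()}: data frame with \code{patient_id},
#'   \code{item}, \code{quantity}.
#' @export
read_utilization <- function(path) {
  validate_utilization(read_pipeline_csv(path, c("patient_id", "item", "quantity")))
}

#' @rdname read_utilization
#' @export
write_utilization <- function(utilization, path, metadata = NULL) {
  write_pipeline_csv(as.data.frame(utilization)[c("patient_id", "item", "quantity")],
                     path, metadata)
}

#' Read and write price tables
#'
#' @inheritParams read_patients
#' @param prices A \code{price_table}.
#' @return \code{read_prices()}: a \code{price_table}. The file carries a
#'   \code{currency} column; all rows must agree.
#' @export
read_prices <- function(path) {
  df <- read_pipeline_csv(path, c("item", "unit_cost", "kind", "currency"))
  cur <- unique(df$currency)
  if (length(cur) != 1L)
    stop("price file mixes currencies: ", paste(cur, collapse = ", "),
         call. = FALSE)
  price_table(df$item, as.numeric(df$unit_cost), df$kind, currency = cur)
}

#' @rdname read_prices
#' @export
write_prices <- function(prices, path, metadata = NULL) {
  stopifnot(inherits(prices, "price_table"))
  df <- as.data.frame(prices)
  df$currency <- attr(prices, "currency")
  write_pipeline_csv(df, path, metadata)
}
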