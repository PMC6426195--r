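# Fixture builders and independent oracles shared by the test files.
# Everything is constructed in code; no data files.

toy_prices <- function(currency = "USD") {
  price_table(
    item = c("amoxicillin", "saline_bag", "cp_test", "gm_test",
             "opd_visit", "ipd_day", "operation"),
    unit_cost = c(0.5, 1.2, 1.67, 0.42, 1.60, 2.02, 10.37),
    kind = c("drug", "drug", "laboratory", "laboratory",
             "routine", "routine", "operation"),
    currency = currency)
}

toy_patients <- function(n = 6, categories = NULL, ages = NULL) {
  if (is.null(categories))
    categories <- rep(complication_levels(), length.out = n)
  if (is.null(ages)) ages <- rep(c(22, 34), length.out = n)
  validate_patients(data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    admission_order = seq_len(n),
    age = ages,
    location = rep(c("rural", "urban"), length.out = n),
    anc_received = rep(c(TRUE, FALSE), length.out = n),
    length_of_stay = rep(2:4, length.out = n),
    complication = categories,
    stringsAsFactors = FALSE))
}

# treatment_costs object with given totals (whole amount booked as drug cost)
costs_from_totals <- function(patients, totals, currency = "USD") {
  out <- data.frame(patient_id = patients$patient_id,
                    drug_cost = totals, laboratory_cost = 0,
                    routine_cost = 0, operation_cost = 0,
                    total = totals, stringsAsFactors = FALSE)
  attr(out, "currency") <- currency
  class(out) <- c("treatment_costs", "data.frame")
  out
}

# Minimal cost_design for simulation-style model tests: y on given X.
make_design <- function(X, y, reference = "aph") {
  X <- as.data.frame(X)
  structure(list(y = y, X = X, reference = reference,
                 candidates = names(X),
                 patient_id = sprintf("D%04d", seq_along(y)),
                 patients = NULL, costs = NULL),
            class = "cost_design")
}

# Random admissible ledger: 2 TCCs, 3 ACCs, TCC-to-TCC shares <= 0.5.
random_ledger <- function() {
  centers <- data.frame(
    center = c("t1", "t2", "a1", "a2", "a3"),
    role = c("TCC", "TCC", "ACC", "ACC", "ACC"),
    labor_cost = stats::runif(5, 10, 100),
    material_cost = stats::runif(5, 5, 50),
    stringsAsFactors = FALSE)
  assets <- data.frame(asset = paste0("eq", 1:5),
                       center = centers$center,
                       replacement_cost = stats::runif(5, 0, 500),
                       useful_life = sample(1:20, 5, replace = TRUE),
                       stringsAsFactors = FALSE)
  base_row <- function(provider, other_tcc) {
    to_tcc <- stats::runif(1, 0, 0.5)
    to_accs <- stats::runif(3)
    to_accs <- to_accs / sum(to_accs) * (1 - to_tcc)
    data.frame(provider = provider,
               receiver = c(other_tcc, "a1", "a2", "a3"),
               volume = c(to_tcc, to_accs) * stats::runif(1, 10, 1000),
               stringsAsFactors = FALSE)
  }
  bases <- rbind(base_row("t1", "t2"), base_row("t2", "t1"))
  outputs <- data.frame(center = c("a1", "a2", "a3"),
                        volume = stats::runif(3, 100, 1000))
  cost_ledger(centers, assets, bases, outputs)
}

# Fixed-point iterative allocation, the independent oracle for the
# simultaneous-equation solution.
iterative_allocation <- function(ledger, rate = 0.03, iterations = 300) {
  dc <- center_direct_costs(ledger, rate = rate)
  d <- stats::setNames(dc$direct_cost, dc$center)
  tccs <- dc$center[dc$role == "TCC"]
  accs <- dc$center[dc$role == "ACC"]
  ab <- ledger$allocation_bases
  shares <- matrix(0, length(tccs), length(dc$center),
                   dimnames = list(tccs, dc$center))
  for (tcc in tccs) {
    rows <- ab[ab$provider == tcc, ]
    shares[tcc, rows$receiver] <- rows$volume / sum(rows$volume)
  }
  X <- d[tccs]
  for (i in seq_len(iterations))
    X <- d[tccs] + drop(t(shares[, tccs, drop = FALSE]) %*% X)
  full <- d[accs] + drop(t(shares[, accs, drop = FALSE]) %*% X)
  stats::setNames(full, accs)
}

# Published-model coefficient vector used in prediction tests (log-MMK scale).
published_coefficients <- function() {
  c(`(Intercept)` = 9.602, incomplete_abortion = 0.901,
    prolonged_labor = 0.947, pph = 0.649, pih = 0.407,
    age = 0.006, septicemia = 0.133)
}
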