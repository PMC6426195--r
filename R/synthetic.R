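#' @title Synthetic cohorts, utilization, prices and hospital ledgers
#' @description Generators that emulate the statistical structure the
#'   analysis assumes — a small obstetric-complication cohort with realistic
#'   demographics, per-patient costs drawn from the log-linear generative
#'   model, itemized utilization that prices back to those costs, and a
#'   plausible (entirely fictional) township-hospital ledger — so that every
#'   pipeline stage runs and is testable without patient data.
#' @name synthetic_data
NULL

#' Bundled service price table
#'
#' Unit costs of the basic medical services of a 25-bed township hospital
#' (USD, 2015 values), plus a handful of synthetic composite drug items
#' (real drug invoices are itemized per product; the composites stand in for
#' them and are synthetic, not observed prices).
#'
#' @return A [price_table()] in USD.
#' @export
default_price_table <- function() {
  services <- data.frame(
    item = c("operation", "opd_visit", "ipd_admission", "ipd_patient_day",
             "adult_chest_xray", "limb_xray", "child_xray",
             "hiv_test", "hbsag_test", "hcv_test", "vdrl_test", "hb_test",
             "complete_picture", "rbs_test", "esr_test", "pcv_test",
             "bt_ct_test", "grouping_matching", "rh_group_test",
             "mp_film_test", "mp_ict_test", "zn_stain_test",
             "urine_re", "urine_re_strip", "ucg_test", "stool_re"),
    unit_cost = c(10.37, 1.60, 9.48, 2.02,
                  6.97, 6.74, 6.67,
                  3.15, 0.56, 1.04, 0.77, 0.25,
                  1.67, 0.40, 4.07, 0.43,
                  0.75, 0.42, 0.40,
                  1.22, 1.03, 1.06,
                  1.38, 0.44, 0.11, 0.66),
    kind = c("operation", "routine", "routine", "routine",
             rep("laboratory", 22)),
    stringsAsFactors = FALSE)
  # synthetic composite drug items (per-course bundles, not observed prices)
  drugs <- data.frame(
    item = c("drug_sundries", "antibiotic_course", "iv_fluid_set",
             "oxytocin_ampoule"),
    unit_cost = c(1.00, 2.50, 1.20, 0.80),
    kind = "drug", stringsAsFactors = FALSE)
  both <- rbind(services, drugs)
  price_table(both$item, both$unit_cost, both$kind, currency = "USD")
}

#' Generative coefficients of the log-cost model
#'
#' Default coefficient vector of the synthetic cohort's data-generating
#' process, on the natural-log MMK scale: intercept, the significant
#' complication effects relative to the APH reference, and an age slope.
#' Urban location, ANC receipt and PID (a singleton category in the
#' motivating cohort, with no fitted effect) default to null effects.
#'
#' @return Named numeric vector usable as the \code{beta} of
#'   [cohort_params()] or in [fixed_cost_model()].
#' @export
default_coefficients <- function() {
  c(`(Intercept)` = 9.602,
    incomplete_abortion = 0.901,
    prolonged_labor = 0.947,
    pph = 0.649,
    pih = 0.407,
    septicemia = 0.133,
    pid = 0,
    age = 0.006,
    urban = 0,
    anc = 0)
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults describe a one-year obstetric-complication caseload of a small
#' township hospital: 91 cases across seven categories, ages centred on the
#' mid-twenties, two-thirds rural, high ANC coverage, stays of 2 to 5 days,
#' and log-normal treatment costs generated from [default_coefficients()]
#' with small log-scale noise.
#'
#' @param n Cohort size.
#' @param category_probs Named 7-vector of category probabilities (summing
#'   to 1).
#' @param age_mean,age_sd,age_bounds Truncated-normal age distribution in
#'   years, rounded to integers.
#' @param rural_prob Probability of rural residence.
#' @param anc_prob Probability of having received antenatal care.
#' @param los_probs Named probability vector over length-of-stay days.
#' @param beta Generative log-cost coefficients (MMK log scale).
#' @param sigma Log-scale noise standard deviation.
#' @return A list of class \code{cohort_params}.
#' @export
cohort_params <- function(n = 91,
                          category_probs = c(incomplete_abortion = 26, pid = 1,
                                             pih = 23, aph = 11, pph = 17,
                                             prolonged_labor = 9,
                                             septicemia = 4) / 91,
                          age_mean = 26.75, age_sd = 5.09,
                          age_bounds = c(19, 39),
                          rural_prob = 0.659, anc_prob = 0.846,
                          los_probs = c(`2` = 0.22, `3` = 0.50,
                                        `4` = 0.22, `5` = 0.06),
                          beta = default_coefficients(),
                          sigma = 0.1) {
  stopifnot(n >= 1, sigma >= 0,
            all(category_probs >= 0), all(category_probs <= 1),
            abs(sum(category_probs) - 1) < 1e-8,
            abs(sum(los_probs) - 1) < 1e-8,
            rural_prob >= 0, rural_prob <= 1, anc_prob >= 0, anc_prob <= 1,
            setequal(names(category_probs), complication_levels()),
            "(Intercept)" %in% names(beta))
  structure(list(n = as.integer(n), category_probs = category_probs,
                 age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
                 rural_prob = rural_prob, anc_prob = anc_prob,
                 los_probs = los_probs, beta = beta, sigma = sigma),
            class = "cohort_params")
}

# Truncated-normal integer draws whose truncated mean equals the requested
# mean: the location of the underlying normal is shifted to undo the
# truncation bias (asymmetric bounds would otherwise pull the mean).
rtruncnorm_int <- function(n, mean, sd, bounds) {
  trunc_mean <- function(mu) {
    a <- (bounds[1] - mu) / sd; b <- (bounds[2] - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                       interval = mean + c(-3, 3) * sd, tol = 1e-10)$root
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mu, sd)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Generate a synthetic patient cohort with latent true costs
#'
#' Draws demographics independently from the configured margins and a latent
#' total treatment cost per patient from the log-linear generative model
#' \eqn{\ln(cost_{MMK}) = \beta_0 + \beta_{cat} + \beta_{age} age + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma)}. Fully reproducible given a seed.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed; \code{NULL} to use the current RNG stream.
#' @return List with \code{patients} (validated cohort data frame) and
#'   \code{latent} (data frame of \code{patient_id}, \code{log_cost_mmk},
#'   \code{cost_mmk}).
#' @export
generate_cohort <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  complication <- sample(names(params$category_probs), n, replace = TRUE,
                         prob = params$category_probs)
  age <- rtruncnorm_int(n, params$age_mean, params$age_sd, params$age_bounds)
  location <- ifelse(stats::runif(n) < params$rural_prob, "rural", "urban")
  anc <- stats::runif(n) < params$anc_prob
  los <- as.integer(sample(names(params$los_probs), n, replace = TRUE,
                           prob = params$los_probs))
  beta <- params$beta
  coef_of <- function(name) if (name %in% names(beta)) beta[[name]] else 0
  lp <- beta[["(Intercept)"]] +
    vapply(complication, coef_of, numeric(1)) +
    coef_of("age") * age +
    coef_of("urban") * (location == "urban") +
    coef_of("anc") * anc
  log_cost <- lp + stats::rnorm(n, 0, params$sigma)
  patients <- validate_patients(data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    admission_order = seq_len(n),
    age = age, location = location, anc_received = anc,
    length_of_stay = los, complication = complication,
    stringsAsFactors = FALSE))
  list(patients = patients,
       latent = data.frame(patient_id = patients$patient_id,
                           log_cost_mmk = unname(log_cost),
                           cost_mmk = unname(exp(log_cost)),
                           stringsAsFactors = FALSE))
}

# Typical per-category cost-component profiles (USD medians) used to
# decompose a latent total into drug / laboratory / routine / operation
# amounts with realistic proportions.
category_cost_profile <- function() {
  m <- rbind(incomplete_abortion = c(10.36, 9.38, 6.05, 10.37),
             pid                 = c(7.96, 0.40, 7.65, 0),
             pih                 = c(9.30, 3.86, 9.67, 0),
             aph                 = c(2.87, 9.78, 1.60, 0),
             pph                 = c(4.45, 9.78, 1.60, 10.37),
             prolonged_labor     = c(11.67, 9.78, 6.05, 10.37),
             septicemia          = c(6.34, 0, 10.68, 0))
  colnames(m) <- cost_components()
  m
}

#' Itemized utilization realizing a latent treatment cost
#'
#' Decomposes each patient's latent total cost into the four components with
#' proportions drawn near the category's typical component profile (small
#' multiplicative jitter, renormalized), then emits one representative priced
#' item per nonzero component with the exact fractional quantity, so that
#' pricing the emitted items reproduces the latent total to well within
#' 0.01 USD. A zero latent cost yields no items.
#'
#' @param patients Cohort data frame from [generate_cohort()].
#' @param latent Matching latent-cost data frame.
#' @param prices A [price_table()] covering the four component kinds.
#' @param exchange_rate MMK per USD, to express latent MMK costs in the
#'   price-table currency.
#' @param jitter_sd Log-scale SD of the component-proportion jitter.
#' @return Long-format utilization data frame (\code{patient_id},
#'   \code{item}, \code{quantity}).
#' @export
realize_utilization <- function(patients, latent, prices = default_price_table(),
                                exchange_rate = 1199.07, jitter_sd = 0.05) {
  stopifnot(inherits(prices, "price_table"))
  profile <- category_cost_profile()
  rep_items <- c(drug = "drug_sundries", laboratory = "complete_picture",
                 routine = "ipd_patient_day", operation = "operation")
  missing_items <- setdiff(rep_items, prices$item)
  if (length(missing_items))
    stop("price table lacks representative item(s): ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  unit <- stats::setNames(prices$unit_cost, prices$item)
  total_in_table_currency <- convert_currency(latent$cost_mmk, "MMK",
                                              attr(prices, "currency"),
                                              exchange_rate)
  rows <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    total <- total_in_table_currency[match(patients$patient_id[i],
                                           latent$patient_id)]
    if (!isTRUE(total > 0)) next
    props <- profile[patients$complication[i], ] *
      exp(stats::rnorm(4, 0, jitter_sd))
    if (sum(props) == 0) {  # degenerate profile: everything to drug sundries
      props <- c(drug = 1, laboratory = 0, routine = 0, operation = 0)
    }
    props <- props / sum(props)
    amounts <- total * props
    keep <- amounts > 0
    rows[[i]] <- data.frame(patient_id = patients$patient_id[i],
                            item = unname(rep_items[names(amounts)[keep]]),
                            quantity = unname(amounts[keep] /
                                                unit[rep_items[names(amounts)[keep]]]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(), item = character(),
                      quantity = numeric(), stringsAsFactors = FALSE)
  validate_utilization(out)
  out
}

#' Generate a plausible synthetic hospital ledger
#'
#' Builds a fictional 25-bed township hospital with five absorbing cost
#' centers (OPD, IPD, laboratory, X-ray, operation theatre) and two
#' transient cost centers (administration, laundry/CSSD). Direct costs are
#' calibrated so the hospital total and its capital/labor/material shares
#' match the configured values; capital enters as building (20-year life)
#' and equipment (5-year life) assets whose annualized costs reproduce each
#' center's capital target at the given discount rate. Output volumes are
#' set so the OPD-visit, IPD-patient-day and operation unit costs emerge
#' near their configured targets. The hospital is an invention: no real
#' facility's books are represented.
#'
#' @param seed Integer seed for the allocation-base jitter; \code{NULL} to
#'   use the current RNG stream.
#' @param rate Discount rate for capital annualization.
#' @param total_cost Total annual hospital cost (USD).
#' @param component_shares Named shares of capital, labor and material in
#'   the total (must sum to 1 within rounding).
#' @param unit_cost_targets Named USD targets for the \code{opd},
#'   \code{ipd} and \code{theatre} unit costs (with \code{laboratory} and
#'   \code{xray} targets for the remaining ACCs).
#' @return A [cost_ledger()] in USD.
#' @export
generate_ledger <- function(seed = NULL, rate = 0.03, total_cost = 88457,
                            component_shares = c(capital = 0.2559,
                                                 labor = 0.5125,
                                                 material = 0.2316),
                            unit_cost_targets = c(opd = 1.60, ipd = 2.02,
                                                  laboratory = 1.05,
                                                  xray = 6.80,
                                                  theatre = 10.37)) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(component_shares) - 1) < 1e-3)
  center_shares <- c(administration = 0.18, laundry_cssd = 0.07,
                     opd = 0.17, ipd = 0.25, laboratory = 0.12,
                     xray = 0.08, theatre = 0.13)
  roles <- c(administration = "TCC", laundry_cssd = "TCC",
             opd = "ACC", ipd = "ACC", laboratory = "ACC",
             xray = "ACC", theatre = "ACC")
  direct <- total_cost * center_shares
  capital_target <- component_shares[["capital"]] * direct
  centers <- data.frame(center = names(center_shares),
                        role = unname(roles[names(center_shares)]),
                        labor_cost = unname(component_shares[["labor"]] * direct),
                        material_cost = unname(component_shares[["material"]] * direct),
                        stringsAsFactors = FALSE)
  assets <- do.call(rbind, lapply(names(center_shares), function(cn) {
    data.frame(asset = paste0(cn, c("_building", "_equipment")),
               center = cn,
               replacement_cost = c(
                 0.6 * capital_target[[cn]] * annuity_factor(rate, 20),
                 0.4 * capital_target[[cn]] * annuity_factor(rate, 5)),
               useful_life = c(20L, 5L), stringsAsFactors = FALSE)
  }))
  jitter <- function(x) x * exp(stats::rnorm(length(x), 0, 0.05))
  bases <- rbind(
    data.frame(provider = "administration",
               receiver = c("laundry_cssd", "opd", "ipd", "laboratory",
                            "xray", "theatre"),
               volume = jitter(c(4, 10, 20, 6, 3, 7)),  # staff supervised
               stringsAsFactors = FALSE),
    data.frame(provider = "laundry_cssd",
               receiver = c("administration", "opd", "ipd", "laboratory",
                            "xray", "theatre"),
               volume = jitter(c(100, 200, 2500, 150, 50, 1000)),  # kg linen
               stringsAsFactors = FALSE))
  # provisional outputs; replaced after the allocation is known
  provisional <- data.frame(center = names(roles)[roles == "ACC"], volume = 1)
  ledger <- cost_ledger(centers, assets, bases, provisional, currency = "USD")
  full <- reciprocal_allocation(ledger, rate = rate)$acc_full_costs
  targets <- c(opd = unit_cost_targets[["opd"]],
               ipd = unit_cost_targets[["ipd"]],
               laboratory = unit_cost_targets[["laboratory"]],
               xray = unit_cost_targets[["xray"]],
               theatre = unit_cost_targets[["theatre"]])
  volumes <- round(full[names(targets)] / targets)
  volumes[volumes < 1] <- 1
  ledger$outputs <- data.frame(center = names(volumes),
                               volume = unname(volumes),
                               stringsAsFactors = FALSE)
  ledger
}

#' Simulate a complete input-file set
#'
#' Runs all generators under one seed and, when \code{dir} is given, writes
#' the full pipeline input set (patients, utilization, prices and the four
#' ledger files), each with a metadata header recording the seed.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed governing every generator.
#' @param dir Optional output directory (created if needed).
#' @param exchange_rate MMK per USD.
#' @return List with \code{patients}, \code{latent}, \code{utilization},
#'   \code{prices}, \code{ledger}, \code{seed} and, when written,
#'   \code{paths}.
#' @export
simulate_dataset <- function(params = cohort_params(), seed = 1L, dir = NULL,
                             exchange_rate = 1199.07) {
  set.seed(seed)
  cohort <- generate_cohort(params, seed = NULL)
  prices <- default_price_table()
  utilization <- realize_utilization(cohort$patients, cohort$latent, prices,
                                     exchange_rate = exchange_rate)
  ledger <- generate_ledger(seed = NULL)
  out <- list(patients = cohort$patients, latent = cohort$latent,
              utilization = utilization, prices = prices, ledger = ledger,
              seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(seed = seed)
    paths <- c(patients = file.path(dir, "patients.csv"),
               utilization = file.path(dir, "utilization.csv"),
               prices = file.path(dir, "prices.csv"))
    write_patients(cohort$patients, paths["patients"], meta)
    write_utilization(utilization, paths["utilization"], meta)
    write_prices(prices, paths["prices"], meta)
    paths <- c(paths, write_ledger(ledger, dir, meta))
    out$paths <- paths
  }
  out
}
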