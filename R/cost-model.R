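#' @title Log-linear treatment-cost regression
#' @description Fit and diagnose the log-linear treatment-cost model:
#'   natural-log total cost (in MMK) regressed on dummy-coded complication
#'   categories plus age, urban location and ANC receipt, with SPSS-style
#'   stepwise selection on the probability of the partial F statistic,
#'   residual and collinearity diagnostics, a single outlier-trimming pass on
#'   studentized deleted residuals, Duan smearing retransformation, and
#'   per-complication predicted costs on the dollar scale.
#' @name cost_model
NULL

#' Settings of the treatment-cost model
#'
#' @param p_enter Entry threshold: a candidate enters when the probability of
#'   its partial F statistic is at most this value (default 0.05).
#' @param p_remove Removal threshold: an included predictor is removed when
#'   its partial-F probability is at least this value (default 0.10). Must
#'   satisfy \code{p_enter <= p_remove}.
#' @param sdr_threshold Outlier cutoff on the absolute studentized deleted
#'   residual (default 2).
#' @param reference Reference complication category, or \code{NULL} to pick
#'   the observed category with the lowest mean treatment cost.
#' @param exchange_rate MMK per USD, used to express costs in the modeling
#'   currency (MMK) and predictions in USD.
#' @return A list of class \code{cost_model_spec}.
#' @export
cost_model_spec <- function(p_enter = 0.05, p_remove = 0.10,
                            sdr_threshold = 2, reference = NULL,
                            exchange_rate = 1199.07) {
  stopifnot(is.numeric(p_enter), p_enter > 0, p_enter <= 1,
            is.numeric(p_remove), p_remove <= 1,
            p_enter <= p_remove,
            is.numeric(sdr_threshold), sdr_threshold > 0,
            is.numeric(exchange_rate), exchange_rate > 0)
  if (!is.null(reference))
    reference <- match.arg(reference, complication_levels())
  structure(list(p_enter = p_enter, p_remove = p_remove,
                 sdr_threshold = sdr_threshold, reference = reference,
                 exchange_rate = exchange_rate),
            class = "cost_model_spec")
}

# Canonical candidate ordering used for deterministic tie-breaking:
# complication dummies in reporting order, then age, urban, ANC.
candidate_order <- function(reference) {
  c(setdiff(complication_levels(), reference), "age", "urban", "anc")
}

#' Build the regression design from costed patient records
#'
#' The response is the natural log of the total treatment cost in MMK.
#' Candidate predictors are one dummy per non-reference complication category
#' observed in the data, patient age in years, an urban-location indicator
#' and an ANC-received indicator. The reference category defaults to the
#' observed category with the lowest mean cost. Rows follow
#' \code{admission_order}, the case ordering used by the Durbin-Watson
#' statistic.
#'
#' @param patients Validated cohort data frame.
#' @param costs Matching \code{treatment_costs} (any currency; converted to
#'   MMK internally).
#' @param spec A [cost_model_spec()].
#' @return A list of class \code{cost_design}: \code{y} (log MMK response),
#'   \code{X} (data frame of candidate predictors in canonical order),
#'   \code{reference}, \code{candidates}, \code{patient_id},
#'   \code{patients}, \code{costs}.
#' @export
build_design <- function(patients, costs, spec = cost_model_spec()) {
  stopifnot(inherits(costs, "treatment_costs"))
  costs <- convert_costs(costs, "MMK", spec$exchange_rate)
  ord <- order(patients$admission_order)
  patients <- patients[ord, , drop = FALSE]
  costs <- costs[match(patients$patient_id, costs$patient_id), , drop = FALSE]
  bad <- which(!(costs$total > 0))
  if (length(bad))
    stop("total cost must be positive for the log model; offending patient(s): ",
         paste(patients$patient_id[bad], collapse = ", "), call. = FALSE)
  reference <- spec$reference
  if (is.null(reference)) {
    mean_by_cat <- tapply(costs$total, patients$complication, mean)
    reference <- names(mean_by_cat)[which.min(mean_by_cat)]
  } else if (!reference %in% patients$complication) {
    stop("reference category '", reference, "' has no observed cases",
         call. = FALSE)
  }
  y <- log(costs$total)
  X <- data.frame(row.names = seq_along(y))
  absent <- character()
  for (cat in setdiff(complication_levels(), reference)) {
    if (!any(patients$complication == cat)) {
      absent <- c(absent, cat)
      next
    }
    X[[cat]] <- as.numeric(patients$complication == cat)
  }
  if (length(absent))
    message("omitting dummies for unobserved categories: ",
            paste(absent, collapse = ", "))
  X$age <- as.numeric(patients$age)
  X$urban <- as.numeric(patients$location == "urban")
  X$anc <- as.numeric(patients$anc_received)
  candidates <- intersect(candidate_order(reference), names(X))
  structure(list(y = y, X = X[candidates], reference = reference,
                 candidates = candidates, patient_id = patients$patient_id,
                 patients = patients, costs = costs),
            class = "cost_design")
}

coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  df_res <- stats::df.residual(fit)
  tq <- stats::qt(0.975, df_res)
  data.frame(term = rownames(sm),
             estimate = sm[, 1], std_error = sm[, 2],
             t_value = sm[, 3], p_value = sm[, 4],
             ci_lower = sm[, 1] - tq * sm[, 2],
             ci_upper = sm[, 1] + tq * sm[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ordinary least-squares fit of the cost model
#'
#' Fits the log-cost response on a chosen subset of the candidate predictors
#' by OLS and packages estimates, inference and residual-based quantities.
#'
#' @param design A [build_design()] result.
#' @param predictors Character vector of predictor names to include
#'   (default: all candidates).
#' @return An object of class \code{cost_model_fit}: \code{coefficients}
#'   (table with estimate, SE, t, p and 95 percent CI), \code{coef} (named
#'   vector), \code{selected}, \code{residuals} in case order,
#'   \code{r_squared}, \code{adj_r_squared}, \code{n}, \code{smearing}
#'   (mean of exponentiated residuals), \code{reference}, and the underlying
#'   \code{lm} object as \code{fit}.
#' @export
fit_cost_model <- function(design, predictors = design$candidates) {
  stopifnot(inherits(design, "cost_design"))
  unknown <- setdiff(predictors, design$candidates)
  if (length(unknown))
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dat <- data.frame(.y = design$y, design$X[predictors])
  names(dat) <- c(".y", predictors)
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit)))
    stop("singular design: collinear column(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  sm <- summary(fit)
  res <- stats::residuals(fit)
  structure(list(coefficients = coef_table(fit),
                 coef = stats::coef(fit),
                 selected = predictors,
                 residuals = unname(res),
                 fitted = unname(stats::fitted(fit)),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 n = length(res),
                 smearing = smearing_factor(res),
                 reference = design$reference,
                 design = design,
                 fit = fit),
            class = "cost_model_fit")
}

#' @export
print.cost_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Log-linear treatment-cost model (n = %d)\n", x$n))
  if (!is.null(x$reference))
    cat("Reference category:", x$reference, "\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print.data.frame(tab, row.names = FALSE)
  if (!is.null(x$r_squared))
    cat(sprintf("R-squared %.3f (adjusted %.3f); smearing factor %.4f\n",
                x$r_squared, x$adj_r_squared, x$smearing))
  invisible(x)
}

# Partial-F probability of adding `candidate` to the model holding `current`:
# with a single added column this equals the two-sided p-value of its t
# statistic. Rank-deficient additions are treated as uninformative (p = 1).
entry_p_value <- function(design, current, candidate) {
  dat <- data.frame(.y = design$y, design$X[c(current, candidate)])
  names(dat) <- c(".y", current, candidate)
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  if (!candidate %in% rownames(cf)) return(1)
  unname(cf[candidate, 4])
}

#' Stepwise predictor selection on partial-F probabilities
#'
#' Forward stepwise selection with backward removal, the procedure SPSS calls
#' "Stepwise": at each round the candidate with the smallest partial-F
#' probability enters if that probability is at most \code{p_enter}; after
#' every entry, any included predictor whose partial-F probability has risen
#' to \code{p_remove} or more is removed (worst first). Iteration stops when
#' no predictor enters or leaves. Ties are broken by the canonical candidate
#' ordering (complication dummies in reporting order, then age, urban
#' location, ANC), so the procedure is deterministic.
#'
#' @param design A [build_design()] result.
#' @param spec A [cost_model_spec()] providing \code{p_enter} and
#'   \code{p_remove}.
#' @return A \code{cost_model_fit} for the selected predictors (intercept-only
#'   when nothing qualifies).
#' @export
stepwise_select <- function(design, spec = cost_model_spec()) {
  stopifnot(inherits(design, "cost_design"))
  current <- character()
  repeat {
    changed <- FALSE
    pool <- setdiff(design$candidates, current)
    if (length(pool)) {
      p_in <- vapply(pool, function(cand) entry_p_value(design, current, cand),
                     numeric(1))
      if (min(p_in) <= spec$p_enter) {
        current <- c(current, pool[which.min(p_in)])
        changed <- TRUE
      }
    }
    repeat {
      if (!length(current)) break
      fit <- fit_cost_model(design, current)
      cf <- fit$coefficients
      inc <- cf[cf$term != "(Intercept)", , drop = FALSE]
      worst <- which.max(inc$p_value)
      if (inc$p_value[worst] >= spec$p_remove) {
        current <- setdiff(current, inc$term[worst])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit_cost_model(design, current)  # predictors kept in entry order
}

#' Durbin-Watson statistic
#'
#' First-order autocorrelation diagnostic on residuals taken in case order:
#' \eqn{d = \sum_{t \ge 2} (e_t - e_{t-1})^2 / \sum_t e_t^2}. Values near 2
#' indicate independent residuals.
#'
#' @param residuals Numeric vector of at least two residuals in case order.
#' @return The statistic \code{d}; \code{NaN} with a warning when all
#'   residuals are zero (undefined).
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2L)
    stop("Durbin-Watson needs at least two residuals", call. = FALSE)
  denom <- sum(residuals^2)
  if (denom == 0) {
    warning("all residuals are zero; Durbin-Watson undefined")
    return(NaN)
  }
  sum(diff(residuals)^2) / denom
}

#' Collinearity diagnostics: tolerance, VIF and condition indices
#'
#' Tolerance of predictor j is \eqn{1 - R^2_j} from regressing it on the
#' other predictors; the variance inflation factor is its reciprocal.
#' Condition indices are \eqn{\sqrt{\lambda_{max}/\lambda_i}} of the
#' cross-product of the unit-length-scaled design including the intercept
#' column (the convention whose smallest index is exactly 1).
#'
#' @param X Data frame or matrix of predictors (no intercept column).
#' @return List with \code{tolerance} and \code{vif} (named by predictor;
#'   \code{NA} when only one predictor), and \code{condition_indices}.
#'   Perfectly collinear predictors get tolerance 0 and infinite VIF.
#' @export
collinearity_diagnostics <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p >= 2L) {
    tol <- vapply(seq_len(p), function(j) {
      fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      rss <- sum(fit$residuals^2)
      tss <- sum((X[, j] - mean(X[, j]))^2)
      if (tss == 0) return(0)
      max(rss / tss, 0)
    }, numeric(1))
    names(tol) <- colnames(X)
    vif <- ifelse(tol > 0, 1 / tol, Inf)
  } else {
    tol <- vif <- stats::setNames(rep(NA_real_, p), colnames(X))
  }
  Z <- cbind(`(Intercept)` = 1, X)
  Z <- sweep(Z, 2, sqrt(colSums(Z^2)), "/")
  d <- svd(Z, nu = 0, nv = 0)$d
  list(tolerance = tol, vif = vif,
       condition_indices = max(d) / pmax(d, .Machine$double.eps))
}

#' Case-level influence diagnostics
#'
#' Studentized deleted residuals (residual scaled by the leave-one-out error
#' estimate) and Cook's distances for every case of a fitted cost model.
#' Cases with leverage 1 have undefined statistics and are flagged.
#'
#' @param fit A \code{cost_model_fit} with an underlying \code{lm} object.
#' @param sdr_threshold Absolute cutoff flagging outliers (default 2).
#' @return Data frame with \code{patient_id}, \code{residual},
#'   \code{leverage}, \code{sdr}, \code{cooks}, \code{outlier},
#'   \code{undefined}.
#' @export
case_diagnostics <- function(fit, sdr_threshold = 2) {
  stopifnot(inherits(fit, "cost_model_fit"), !is.null(fit$fit))
  lev <- unname(stats::hatvalues(fit$fit))
  sdr <- suppressWarnings(unname(stats::rstudent(fit$fit)))
  cooks <- unname(stats::cooks.distance(fit$fit))
  undefined <- lev >= 1 - 1e-12 | !is.finite(sdr)
  data.frame(patient_id = fit$design$patient_id,
             residual = fit$residuals, leverage = lev,
             sdr = sdr, cooks = cooks,
             outlier = !undefined & abs(sdr) > sdr_threshold,
             undefined = undefined,
             stringsAsFactors = FALSE)
}

#' Full diagnostics report against the conventional criteria
#'
#' Durbin-Watson (pass in [1.5, 2.5]), condition index (max at most 30),
#' tolerance (min above 0.1), VIF (max below 10), Cook's distance (max below
#' 1), and studentized-deleted-residual outlier flags.
#'
#' @param fit A \code{cost_model_fit}.
#' @param sdr_threshold Outlier cutoff on |SDR|.
#' @return List of class \code{cost_model_diagnostics} with the statistics,
#'   the per-case table and a logical \code{criteria} vector.
#' @export
model_diagnostics <- function(fit, sdr_threshold = 2) {
  stopifnot(inherits(fit, "cost_model_fit"))
  dw <- durbin_watson(fit$residuals)
  cases <- case_diagnostics(fit, sdr_threshold)
  if (length(fit$selected)) {
    coll <- collinearity_diagnostics(fit$design$X[fit$selected])
  } else {
    coll <- list(tolerance = numeric(0), vif = numeric(0),
                 condition_indices = 1)
  }
  criteria <- c(
    durbin_watson = is.finite(dw) && dw >= 1.5 && dw <= 2.5,
    condition_index = max(coll$condition_indices) <= 30,
    tolerance = !length(coll$tolerance) || all(is.na(coll$tolerance)) ||
      min(coll$tolerance, na.rm = TRUE) > 0.1,
    vif = !length(coll$vif) || all(is.na(coll$vif)) ||
      max(coll$vif, na.rm = TRUE) < 10,
    cooks = all(cases$cooks[!cases$undefined] < 1),
    no_outliers = !any(cases$outlier))
  structure(list(durbin_watson = dw, collinearity = coll, cases = cases,
                 sdr_threshold = sdr_threshold, criteria = criteria),
            class = "cost_model_diagnostics")
}

#' @export
print.cost_model_diagnostics <- function(x, ...) {
  cat(sprintf("Durbin-Watson: %.3f (criteria 1.5-2.5): %s\n", x$durbin_watson,
              ifelse(x$criteria["durbin_watson"], "pass", "FAIL")))
  cat(sprintf("Condition index max: %.3f (<= 30): %s\n",
              max(x$collinearity$condition_indices),
              ifelse(x$criteria["condition_index"], "pass", "FAIL")))
  if (length(x$collinearity$tolerance) && !all(is.na(x$collinearity$tolerance))) {
    cat(sprintf("Tolerance min: %.3f (> 0.1): %s; VIF max: %.3f (< 10): %s\n",
                min(x$collinearity$tolerance, na.rm = TRUE),
                ifelse(x$criteria["tolerance"], "pass", "FAIL"),
                max(x$collinearity$vif, na.rm = TRUE),
                ifelse(x$criteria["vif"], "pass", "FAIL")))
  }
  cat(sprintf("Cook's distance max: %.3f (< 1): %s\n",
              max(x$cases$cooks[!x$cases$undefined]),
              ifelse(x$criteria["cooks"], "pass", "FAIL")))
  cat(sprintf("Outliers (|SDR| > %g): %d\n", x$sdr_threshold,
              sum(x$cases$outlier)))
  invisible(x)
}

#' One-pass outlier trimming and refit
#'
#' Runs the full workflow on the complete cohort: stepwise fit, case
#' diagnostics, a single pass dropping every case whose absolute studentized
#' deleted residual exceeds the threshold, and a fresh stepwise fit on the
#' remaining cases. Both models and the dropped-case list are returned. When
#' trimming empties a complication category its dummy is dropped with a
#' warning.
#'
#' @param patients Validated cohort data frame.
#' @param costs Matching \code{treatment_costs}.
#' @param spec A [cost_model_spec()].
#' @return List of class \code{trimmed_cost_model}: \code{initial} and
#'   \code{trimmed} fits, their \code{initial_diagnostics} and
#'   \code{diagnostics}, and \code{dropped} patient ids.
#' @export
trim_and_refit <- function(patients, costs, spec = cost_model_spec()) {
  design <- build_design(patients, costs, spec)
  initial <- stepwise_select(design, spec)
  diag0 <- model_diagnostics(initial, spec$sdr_threshold)
  dropped <- diag0$cases$patient_id[diag0$cases$outlier]
  if (length(dropped)) {
    keep <- !(patients$patient_id %in% dropped)
    patients2 <- patients[keep, , drop = FALSE]
    costs2 <- costs[costs$patient_id %in% patients2$patient_id, , drop = FALSE]
    attr(costs2, "currency") <- attr(costs, "currency")
    class(costs2) <- class(costs)
    emptied <- setdiff(unique(patients$complication),
                       unique(patients2$complication))
    if (length(emptied))
      warning("trimming emptied complication category(ies): ",
              paste(emptied, collapse = ", "), "; dummy dropped")
    spec2 <- spec
    if (!is.null(spec$reference) && !spec$reference %in% patients2$complication)
      spec2$reference <- NULL
    design2 <- build_design(patients2, costs2, spec2)
    trimmed <- stepwise_select(design2, spec2)
  } else {
    trimmed <- initial
  }
  structure(list(initial = initial, trimmed = trimmed,
                 initial_diagnostics = diag0,
                 diagnostics = model_diagnostics(trimmed, spec$sdr_threshold),
                 dropped = dropped),
            class = "trimmed_cost_model")
}

#' @export
print.trimmed_cost_model <- function(x, ...) {
  cat(sprintf("Outlier-trimmed cost model: n %d -> %d (%d case(s) dropped)\n",
              x$initial$n, x$trimmed$n, length(x$dropped)))
  print(x$trimmed)
  invisible(x)
}

#' Duan smearing factor
#'
#' The mean of the exponentiated (anti-logged) unstandardized residuals of
#' the log-scale fit. Multiplying \code{exp(linear predictor)} by this factor
#' corrects the retransformation bias of predicting on the money scale from a
#' log-scale model. For OLS residuals of a model with an intercept it is at
#' least 1 (Jensen's inequality on mean-zero residuals).
#'
#' @param residuals Numeric vector of log-scale residuals.
#' @return The smearing factor \code{mean(exp(residuals))}.
#' @examples
#' smearing_factor(c(log(2), -log(2)))  # 1.25
#' @export
smearing_factor <- function(residuals) {
  if (!length(residuals)) return(1)
  mean(exp(residuals))
}

#' Assemble a cost model from externally supplied coefficients
#'
#' Builds a minimal \code{cost_model_fit} from a coefficient vector and a
#' smearing factor, so that published or otherwise fixed models can be used
#' for prediction without refitting.
#'
#' @param coefficients Named numeric vector including \code{"(Intercept)"};
#'   other names are complication tokens or covariates (\code{age},
#'   \code{urban}, \code{anc}).
#' @param smearing Smearing factor of the fixed model.
#' @param reference Reference complication category of the dummy coding.
#' @param n Number of cases the fixed model was fitted on, if known.
#' @return A \code{cost_model_fit} usable by [predict_category_cost()].
#' @export
fixed_cost_model <- function(coefficients, smearing = 1,
                             reference = "aph", n = NA_integer_) {
  stopifnot(is.numeric(coefficients), "(Intercept)" %in% names(coefficients),
            is.numeric(smearing), smearing > 0)
  reference <- match.arg(reference, complication_levels())
  structure(list(coefficients = data.frame(term = names(coefficients),
                                           estimate = unname(coefficients),
                                           stringsAsFactors = FALSE),
                 coef = coefficients,
                 selected = setdiff(names(coefficients), "(Intercept)"),
                 residuals = NULL, r_squared = NULL, adj_r_squared = NULL,
                 n = n, smearing = smearing, reference = reference,
                 design = NULL, fit = NULL),
            class = "cost_model_fit")
}

#' Smearing-retransformed predicted cost of a complication
#'
#' Predicted treatment cost in USD for a complication category at a given
#' age: the model's linear predictor (intercept, plus the category's dummy
#' coefficient when it is not the reference, plus the age effect; urban and
#' ANC at their baseline of 0) is exponentiated, multiplied by the smearing
#' factor, and converted from the modeling currency (MMK) to USD.
#'
#' @param fit A \code{cost_model_fit} (fitted or [fixed_cost_model()]).
#' @param category Complication token(s); either the reference or a category
#'   with a coefficient in the model.
#' @param age Age in years at which to predict (a cohort mean, typically).
#' @param smearing Smearing factor; defaults to the model's own.
#' @param exchange_rate MMK per USD.
#' @param digits Display rounding of the USD prediction (default 2);
#'   \code{NULL} for unrounded.
#' @return Named numeric vector of predicted USD costs.
#' @export
predict_category_cost <- function(fit, category, age,
                                  smearing = fit$smearing,
                                  exchange_rate = 1199.07, digits = 2) {
  stopifnot(inherits(fit, "cost_model_fit"))
  cf <- fit$coef
  vapply(category, function(cat) {
    cat <- match.arg(cat, complication_levels())
    b_cat <- if (identical(cat, fit$reference)) 0 else {
      if (!cat %in% names(cf))
        stop("category '", cat, "' is neither the reference nor in the model",
             call. = FALSE)
      cf[[cat]]
    }
    b_age <- if ("age" %in% names(cf)) cf[["age"]] else 0
    usd <- exp(cf[["(Intercept)"]] + b_cat + b_age * age) * smearing /
      exchange_rate
    if (is.null(digits)) usd else round_half_up(usd, digits)
  }, numeric(1))
}
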