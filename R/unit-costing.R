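#' @title Hospital unit costing with reciprocal cost-center allocation
#' @description Full costing of absorbing cost centers (ACCs) from a hospital
#'   ledger: capital assets are annualized at a discount rate, direct costs
#'   (capital + labor + material) are computed per center, transient
#'   cost-center (TCC) costs are allocated to ACCs by solving the reciprocal
#'   simultaneous-equation system, and average unit costs are derived from
#'   annual output volumes.
#' @name unit_costing
NULL

#' Annuity factor for capital annualization
#'
#' The present value of a one-per-year annuity over an asset's useful life,
#' \eqn{\sum_{t=1}^{Y} (1+r)^{-t}}. Dividing a replacement cost by this factor
#' gives the annualized economic cost of the asset. At a zero rate the factor
#' equals the number of years. The factor is strictly decreasing in the rate
#' and strictly increasing in the number of years.
#'
#' @param rate Discount rate as a proportion (default 0.03).
#' @param years Useful life in whole years, at least 1.
#' @return The annuity factor, a positive number.
#' @examples
#' annuity_factor(0.03, 5)   # 4.579707
#' annuity_factor(0, 7)      # 7
#' @export
annuity_factor <- function(rate, years) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("discount rate must be a single non-negative number", call. = FALSE)
  if (!is.numeric(years) || length(years) != 1L || is.na(years) ||
      years < 1 || years != round(years))
    stop("useful life must be a whole number of years >= 1", call. = FALSE)
  sum((1 + rate)^-(seq_len(years)))
}

#' Annualized economic cost of a capital asset
#'
#' @param replacement_cost Non-negative replacement cost of the asset.
#' @param useful_life Useful life in whole years, at least 1.
#' @param rate Discount rate as a proportion.
#' @return Annual equivalent cost: \code{replacement_cost /
#'   annuity_factor(rate, useful_life)}.
#' @examples
#' annualize_asset(1000, 5, 0.03)  # 218.35 per year
#' @export
annualize_asset <- function(replacement_cost, useful_life, rate = 0.03) {
  if (any(replacement_cost < 0))
    stop("replacement cost must be non-negative", call. = FALSE)
  replacement_cost / annuity_factor(rate, useful_life)
}

#' Construct a hospital cost-center ledger
#'
#' A \code{cost_ledger} bundles the inputs of the unit-costing stage:
#' cost centers with their role (ACC or TCC) and annual labor and material
#' costs, capital assets owned by centers, allocation-base volumes from each
#' TCC to receiving centers, and annual output volumes of the ACCs.
#'
#' @param centers Data frame with columns \code{center}, \code{role}
#'   (\code{"ACC"} or \code{"TCC"}), \code{labor_cost}, \code{material_cost}.
#' @param assets Data frame with columns \code{asset}, \code{center},
#'   \code{replacement_cost}, \code{useful_life}. May be empty.
#' @param allocation_bases Data frame with columns \code{provider} (a TCC),
#'   \code{receiver} (any other center) and non-negative \code{volume};
#'   a TCC's shares are its base volumes row-normalized. Self-allocation
#'   entries must be absent or zero. Every TCC needs a positive total base.
#' @param outputs Data frame with columns \code{center} (an ACC) and positive
#'   annual \code{volume}.
#' @param currency Currency code of all money amounts in the ledger.
#' @return An object of class \code{cost_ledger}.
#' @export
cost_ledger <- function(centers, assets, allocation_bases, outputs,
                        currency = "USD") {
  stopifnot(all(c("center", "role", "labor_cost", "material_cost") %in% names(centers)),
            all(c("provider", "receiver", "volume") %in% names(allocation_bases)),
            all(c("center", "volume") %in% names(outputs)))
  if (is.null(assets) || nrow(assets) == 0L)
    assets <- data.frame(asset = character(), center = character(),
                         replacement_cost = numeric(), useful_life = integer())
  stopifnot(all(c("asset", "center", "replacement_cost", "useful_life") %in% names(assets)))
  centers$role <- toupper(centers$role)
  if (!all(centers$role %in% c("ACC", "TCC")))
    stop("center role must be 'ACC' or 'TCC'", call. = FALSE)
  if (!any(centers$role == "ACC"))
    stop("ledger needs at least one absorbing cost center", call. = FALSE)
  if (anyDuplicated(centers$center))
    stop("duplicate center names", call. = FALSE)
  bad_owner <- setdiff(assets$center, centers$center)
  if (length(bad_owner))
    stop("capital assets owned by unknown center(s): ",
         paste(bad_owner, collapse = ", "), call. = FALSE)
  tccs <- centers$center[centers$role == "TCC"]
  bad_provider <- setdiff(allocation_bases$provider, tccs)
  if (length(bad_provider))
    stop("allocation bases from non-TCC provider(s): ",
         paste(bad_provider, collapse = ", "), call. = FALSE)
  if (any(allocation_bases$volume < 0))
    stop("allocation-base volumes must be non-negative", call. = FALSE)
  self <- allocation_bases$provider == allocation_bases$receiver
  if (any(self & allocation_bases$volume > 0))
    stop("a TCC cannot allocate to itself", call. = FALSE)
  for (tcc in tccs) {
    tot <- sum(allocation_bases$volume[allocation_bases$provider == tcc])
    if (!isTRUE(tot > 0))
      stop("TCC '", tcc, "' has no positive allocation base", call. = FALSE)
  }
  if (any(outputs$volume <= 0))
    stop("ACC output volumes must be positive", call. = FALSE)
  structure(list(centers = centers, assets = assets,
                 allocation_bases = allocation_bases, outputs = outputs,
                 currency = match.arg(currency, c("MMK", "USD"))),
            class = "cost_ledger")
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat(sprintf("Cost-center ledger: %d ACCs, %d TCCs, %d capital assets (%s)\n",
              sum(x$centers$role == "ACC"), sum(x$centers$role == "TCC"),
              nrow(x$assets), x$currency))
  invisible(x)
}

#' Annual direct costs of every cost center
#'
#' Direct cost of a center is its annualized capital cost plus annual labor
#' and material costs. Direct costs are additive: splitting a cost component
#' across pseudo-centers preserves the total.
#'
#' @param ledger A \code{cost_ledger}.
#' @param rate Discount rate used to annualize capital assets.
#' @return Data frame with one row per center: \code{center}, \code{role},
#'   \code{capital_cost}, \code{labor_cost}, \code{material_cost},
#'   \code{direct_cost}.
#' @export
center_direct_costs <- function(ledger, rate = 0.03) {
  stopifnot(inherits(ledger, "cost_ledger"))
  centers <- ledger$centers
  capital <- vapply(centers$center, function(cn) {
    a <- ledger$assets[ledger$assets$center == cn, , drop = FALSE]
    if (nrow(a) == 0L) return(0)
    sum(mapply(annualize_asset, a$replacement_cost, a$useful_life,
               MoreArgs = list(rate = rate)))
  }, numeric(1))
  data.frame(center = centers$center, role = centers$role,
             capital_cost = unname(capital),
             labor_cost = centers$labor_cost,
             material_cost = centers$material_cost,
             direct_cost = unname(capital) + centers$labor_cost +
               centers$material_cost,
             stringsAsFactors = FALSE)
}

# Row-normalized allocation shares of each TCC over all receiving centers.
allocation_shares <- function(ledger) {
  tccs <- ledger$centers$center[ledger$centers$role == "TCC"]
  all_centers <- ledger$centers$center
  shares <- matrix(0, nrow = length(tccs), ncol = length(all_centers),
                   dimnames = list(tccs, all_centers))
  ab <- ledger$allocation_bases
  for (tcc in tccs) {
    rows <- ab[ab$provider == tcc, , drop = FALSE]
    bad <- setdiff(rows$receiver, all_centers)
    if (length(bad))
      stop("allocation base to unknown receiver(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    shares[tcc, rows$receiver] <- rows$volume / sum(rows$volume)
  }
  shares
}

#' Reciprocal (simultaneous-equation) allocation of TCC costs to ACCs
#'
#' Solves the full reciprocal system for the transient centers: each TCC's
#' full cost is its direct cost plus the shares of every other TCC's full
#' cost it receives, \eqn{X_j = D_j + \sum_k a_{kj} X_k}. Each ACC's full
#' cost is then its direct cost plus its shares of the TCC full costs. Money
#' is conserved: the ACC full costs sum to the total direct cost of all
#' centers.
#'
#' @param ledger A \code{cost_ledger}.
#' @param rate Discount rate for capital annualization.
#' @return List with \code{acc_full_costs} (named vector over ACCs),
#'   \code{tcc_full_costs} (named vector over TCCs), \code{direct_costs}
#'   (the [center_direct_costs()] table) and \code{shares} (the TCC share
#'   matrix).
#' @export
reciprocal_allocation <- function(ledger, rate = 0.03) {
  stopifnot(inherits(ledger, "cost_ledger"))
  dc <- center_direct_costs(ledger, rate = rate)
  shares <- allocation_shares(ledger)
  tccs <- rownames(shares)
  accs <- dc$center[dc$role == "ACC"]
  d <- stats::setNames(dc$direct_cost, dc$center)
  if (length(tccs) == 0L) {
    return(list(acc_full_costs = d[accs], tcc_full_costs = numeric(0),
                direct_costs = dc, shares = shares))
  }
  # X = D_T + A' X with A[k, j] the share of TCC k sent to TCC j
  A <- shares[, tccs, drop = FALSE]
  M <- diag(length(tccs)) - t(A)
  if (abs(det(M)) < 1e-12)
    stop("reciprocal share system is singular for TCC(s): ",
         paste(tccs, collapse = ", "),
         "; each TCC must send a positive share outside the TCC set",
         call. = FALSE)
  X <- solve(M, d[tccs])
  names(X) <- tccs
  acc_full <- d[accs] + drop(crossprod(shares[, accs, drop = FALSE], X))
  names(acc_full) <- accs
  list(acc_full_costs = acc_full, tcc_full_costs = X,
       direct_costs = dc, shares = shares)
}

#' Average unit cost of a service
#'
#' @param full_cost Annual full cost of the producing center.
#' @param output_volume Annual output volume, strictly positive.
#' @return Unit cost \code{full_cost / output_volume}.
#' @export
unit_cost_average <- function(full_cost, output_volume) {
  if (any(!is.finite(output_volume)) || any(output_volume <= 0))
    stop("output volume must be positive", call. = FALSE)
  full_cost / output_volume
}

#' Unit costs of all absorbing cost centers
#'
#' Runs the full unit-costing stage: annualize capital, compute direct costs,
#' allocate TCC costs reciprocally, and divide each ACC's full cost by its
#' annual output volume.
#'
#' @param ledger A \code{cost_ledger}.
#' @param rate Discount rate for capital annualization.
#' @return Data frame with one row per ACC: \code{center}, \code{full_cost},
#'   \code{output_volume}, \code{unit_cost}; the ledger currency is attached
#'   as attribute \code{currency}.
#' @export
compute_unit_costs <- function(ledger, rate = 0.03) {
  alloc <- reciprocal_allocation(ledger, rate = rate)
  full <- alloc$acc_full_costs
  missing_out <- setdiff(names(full), ledger$outputs$center)
  if (length(missing_out))
    stop("no output volume for ACC(s): ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  vol <- stats::setNames(ledger$outputs$volume, ledger$outputs$center)[names(full)]
  out <- data.frame(center = names(full), full_cost = unname(full),
                    output_volume = unname(vol),
                    unit_cost = unname(unit_cost_average(full, vol)),
                    stringsAsFactors = FALSE)
  attr(out, "currency") <- ledger$currency
  out
}

#' Read a cost-center ledger from its four CSV files
#'
#' @param centers_path,assets_path,bases_path,outputs_path Paths to the four
#'   ledger files (centers, capital assets, allocation bases, ACC outputs).
#' @param currency Currency of the ledger's money amounts.
#' @return A \code{cost_ledger}.
#' @export
read_ledger <- function(centers_path, assets_path, bases_path, outputs_path,
                        currency = "USD") {
  centers <- read_pipeline_csv(centers_path,
                               c("center", "role", "labor_cost", "material_cost"))
  assets <- read_pipeline_csv(assets_path,
                              c("asset", "center", "replacement_cost", "useful_life"))
  bases <- read_pipeline_csv(bases_path, c("provider", "receiver", "volume"))
  outputs <- read_pipeline_csv(outputs_path, c("center", "volume"))
  cost_ledger(centers, assets, bases, outputs, currency = currency)
}

#' Write a cost-center ledger to its four CSV files
#'
#' @param ledger A \code{cost_ledger}.
#' @param dir Output directory.
#' @param metadata Named list written as comment lines in each file.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_ledger <- function(ledger, dir, metadata = NULL) {
  stopifnot(inherits(ledger, "cost_ledger"))
  paths <- c(centers = file.path(dir, "cost_centers.csv"),
             assets = file.path(dir, "capital_assets.csv"),
             bases = file.path(dir, "allocation_bases.csv"),
             outputs = file.path(dir, "outputs.csv"))
  write_pipeline_csv(ledger$centers, paths["centers"], metadata)
  write_pipeline_csv(ledger$assets, paths["assets"], metadata)
  write_pipeline_csv(ledger$allocation_bases, paths["bases"], metadata)
  write_pipeline_csv(ledger$outputs, paths["outputs"], metadata)
  invisible(paths)
}
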