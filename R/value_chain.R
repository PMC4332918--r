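#' Create a value-chain cost component
#'
#' A single per-unit cost stage in the commodity value chain, from factory
#' gate to retail, tagged with the payer that finances it. Amounts are in
#' 2010 US dollars per kit and are carried internally in exact cents so
#' that per-unit aggregates reproduce printed table values to the cent.
#'
#' @param name Short label for the stage (e.g. `"factory"`, `"retail"`).
#' @param amount Non-negative cost added at this stage, USD per unit.
#' @param payer One of `"donor"`, `"household"`, `"provider"`.
#' @param stage_order Ordinal position of the stage in the chain.
#'
#' @return A one-row `data.frame` with columns `name`, `amount`, `payer`,
#'   `stage_order`.
#' @export
cost_component <- function(name, amount, payer, stage_order) {
  if (!is.numeric(amount) || length(amount) != 1L || is.na(amount) ||
      amount < 0) {
    invalid_parameter("cost component amount must be a non-negative number")
  }
  payer <- match.arg(payer, c("donor", "household", "provider"))
  data.frame(
    name = as.character(name),
    amount = round(amount * 100) / 100,
    payer = payer,
    stage_order = as.integer(stage_order),
    stringsAsFactors = FALSE
  )
}

#' Assemble a commodity value chain
#'
#' Binds ordered cost components into a value chain together with the
#' household-facing retail price and the donor-financed subsidy. Two
#' decompositions of the unit social cost coexist: by cost-bearing stage
#' (who incurs the resource cost) and by financing source (who ultimately
#' pays); [subsidy_ledger()] exposes both.
#'
#' @param components A `data.frame` of stacked [cost_component()] rows.
#' @param retail_price Price paid by the household per unit, USD.
#' @param subsidy Donor-financed markdown per unit, USD.
#'
#' @return An object of class `value_chain`.
#' @export
value_chain <- function(components, retail_price, subsidy) {
  stopifnot(is.data.frame(components), nrow(components) >= 1L)
  if (anyDuplicated(components$stage_order)) {
    invalid_parameter("stage_order must be unique within a value chain")
  }
  if (any(components$amount < 0)) {
    invalid_parameter("value-chain component amounts must be non-negative")
  }
  components <- components[order(components$stage_order), , drop = FALSE]
  structure(
    list(
      components = components,
      retail_price = retail_price,
      subsidy = subsidy
    ),
    class = "value_chain"
  )
}

#' Unit social cost of the commodity
#'
#' The full per-unit resource cost to society: the sum of every value-added
#' stage in the chain regardless of payer. The subsidy moves money between
#' payers but does not reduce this cost.
#'
#' @param chain A [value_chain()].
#' @return Unit social cost, USD per unit (exact cents).
#' @export
unit_social_cost <- function(chain) {
  stopifnot(inherits(chain, "value_chain"))
  if (any(chain$components$amount < 0)) {
    invalid_parameter("value-chain component amounts must be non-negative")
  }
  # sum in integer cents to avoid drift
  sum(round(chain$components$amount * 100)) / 100
}

#' Payer ledger for a value chain
#'
#' Decomposes the unit social cost two ways: `by_stage` sums component
#' amounts by the payer tag on each stage (who incurs the cost), and
#' `by_financing` splits the same total into the household-paid retail
#' price and the donor-financed subsidy (who ultimately pays, with the
#' provider's wholesale outlay and retail revenue netting to their margin).
#' Both decompositions sum to [unit_social_cost()] exactly.
#'
#' @param chain A [value_chain()].
#' @return A list with named numeric vectors `by_stage` and `by_financing`,
#'   and `total` (the unit social cost).
#' @export
subsidy_ledger <- function(chain) {
  stopifnot(inherits(chain, "value_chain"))
  total <- unit_social_cost(chain)
  cents <- round(chain$components$amount * 100)
  by_stage <- tapply(cents, chain$components$payer, sum) / 100
  by_stage <- by_stage[order(names(by_stage))]
  by_financing <- c(household = chain$retail_price, donor = chain$subsidy)
  list(
    by_stage = unlist(as.list(by_stage)),
    by_financing = by_financing,
    total = total
  )
}

#' Amortize product-launch sunk costs over forecast sales
#'
#' Straight-line depreciation of the one-time launch outlay across the
#' depreciation horizon, apportioned to every unit the program expects to
#' sell over that horizon. An optional annual discount rate converts the
#' straight line into an annuity-equivalent per-unit charge; the default
#' (0) is plain straight-line.
#'
#' @param total_launch_cost Total sunk launch cost, USD.
#' @param horizon_years Depreciation horizon in years (default 10).
#' @param annual_forecast_units Forecast units sold per year.
#' @param discount_rate Optional annual discount rate applied to the
#'   horizon (default 0, i.e. undiscounted straight-line).
#' @return Launch cost per unit, USD.
#' @export
amortize_launch <- function(total_launch_cost, horizon_years = 10,
                            annual_forecast_units, discount_rate = 0) {
  if (total_launch_cost < 0) {
    invalid_parameter("total launch cost must be non-negative")
  }
  if (horizon_years <= 0 || annual_forecast_units <= 0) {
    invalid_parameter("horizon and forecast units must be positive")
  }
  if (discount_rate == 0) {
    return(total_launch_cost / (horizon_years * annual_forecast_units))
  }
  # annuity-equivalent units: discounted stream of annual forecasts
  disc_units <- annual_forecast_units *
    (1 - (1 + discount_rate)^(-horizon_years)) / discount_rate
  total_launch_cost / disc_units
}

#' Allocate shared organizational overhead to one product
#'
#' Two-level allocation: the program's share of the organization's total
#' overhead, then the product's share within the program (e.g. the
#' franchise program is ~33% of the organization's work, and the product's
#' share of franchise commodity costs gives the second factor), divided by
#' annual units distributed.
#'
#' @param total_org_overhead Organization-wide overhead, USD per year.
#' @param program_share Fraction of overhead attributable to the program,
#'   in \[0, 1\].
#' @param product_share Fraction of the program attributable to the
#'   product, in \[0, 1\].
#' @param units Annual units of the product distributed.
#' @return Overhead cost per unit, USD.
#' @export
allocate_overhead <- function(total_org_overhead, program_share,
                              product_share, units) {
  if (program_share < 0 || program_share > 1 ||
      product_share < 0 || product_share > 1) {
    invalid_parameter("overhead shares must lie in [0, 1]")
  }
  if (units <= 0) invalid_parameter("units must be positive")
  if (total_org_overhead < 0) {
    invalid_parameter("overhead must be non-negative")
  }
  total_org_overhead * program_share * product_share / units
}

#' Read / write a value chain as delimited text
#'
#' CSV schema: `name, amount_usd, payer, stage_order`. The retail price and
#' subsidy travel as attributes encoded in two pseudo-rows is avoided;
#' instead they are passed explicitly on read.
#'
#' @param path File path.
#' @param chain A [value_chain()] (for writing).
#' @param retail_price,subsidy Financing split supplied on read.
#' @return `read_value_chain()` returns a [value_chain()];
#'   `write_value_chain()` returns `path` invisibly.
#' @export
read_value_chain <- function(path, retail_price, subsidy) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "amount_usd", "payer", "stage_order")
  if (!all(need %in% names(df))) {
    invalid_parameter(
      paste("value-chain CSV must have columns:", paste(need, collapse = ", "))
    )
  }
  comps <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    cost_component(df$name[i], df$amount_usd[i], df$payer[i],
                   df$stage_order[i])
  }))
  value_chain(comps, retail_price = retail_price, subsidy = subsidy)
}

#' @rdname read_value_chain
#' @export
write_value_chain <- function(chain, path) {
  stopifnot(inherits(chain, "value_chain"))
  df <- chain$components
  names(df)[names(df) == "amount"] <- "amount_usd"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
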