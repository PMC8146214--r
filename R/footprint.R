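#' Carbon footprint of milk
#'
#' Net GWP per unit of energy-corrected milk, aggregated over trial years as
#' the mean of yearly ratios (each year's emission intensity weighted
#' equally). The ratio of multi-year means is reported alongside in the
#' pipeline summary.
#'
#' @param yearly_gwp_net Net GWP per year, t CO2eq/ha.
#' @param yearly_milk Milk yield per year, t ECM/ha.
#' @return Carbon footprint, kg CO2eq per kg ECM.
#' @examples
#' carbon_footprint(21.2, 16.6)  # ~1.28
#' @export
carbon_footprint <- function(yearly_gwp_net, yearly_milk) {
  assert_number(yearly_gwp_net, "yearly_gwp_net", allow_vector = TRUE)
  assert_number(yearly_milk, "yearly_milk", allow_vector = TRUE)
  if (length(yearly_gwp_net) != length(yearly_milk)) {
    stop("yearly GWP and milk series must have equal length", call. = FALSE)
  }
  if (any(yearly_milk <= 0)) {
    stop("milk yield must be positive in every year", call. = FALSE)
  }
  mean(yearly_gwp_net / yearly_milk)
}

#' Land requirement of milk production
#'
#' Hectare-to-milk reciprocal: square metres of pasture needed per kg of
#' energy-corrected milk.
#'
#' @param milk_yield Milk yield, t ECM/ha (vectorized).
#' @return Land requirement, m2 per kg ECM.
#' @examples
#' land_requirement(10)  # 1
#' @export
land_requirement <- function(milk_yield) {
  assert_number(milk_yield, "milk_yield", allow_vector = TRUE)
  if (any(milk_yield <= 0)) stop("milk yield must be positive", call. = FALSE)
  10000 / (milk_yield * 1000)
}

#' Contribution of each inventory item to gross GWP
#'
#' Percent share of each non-soil-carbon line item in the gross GWP. Shares
#' sum to 100.
#'
#' @param items Inventory data.frame with columns `item`, `gas`, `co2eq`
#'   (e.g. one treatment's mean inventory).
#' @return data.frame with `item` and `share_pct`.
#' @export
contribution_shares <- function(items) {
  stopifnot(all(c("item", "gas", "co2eq") %in% names(items)))
  keep <- items$gas != "co2_soc"
  gross <- sum(items$co2eq[keep])
  if (gross <= 0) stop("gross GWP must be positive", call. = FALSE)
  data.frame(item = items$item[keep],
             share_pct = 100 * items$co2eq[keep] / gross,
             stringsAsFactors = FALSE)
}

#' Cross-treatment relationships of emissions and milk with the farm balance
#'
#' Fits both a linear model `y = a + b x` and a three-parameter exponential
#' `y = a + b exp(c x)` of a response against the farm-N-balance, by least
#' squares (the exponential by profiling `c` with the conditionally linear
#' `a`, `b` solved exactly). Returns coefficients, residual sums of squares,
#' an AIC for each and the AIC-preferred model. The exponential family nests
#' the linear model (as c -> 0), so raw RSS always favours it weakly; the
#' AIC comparison is what distinguishes a genuinely curved relationship from
#' a linear one.
#'
#' @param balance Farm-N-balance per treatment, kg N/ha.
#' @param response Response per treatment (e.g. net GWP t CO2eq/ha, or milk
#'   t ECM/ha).
#' @param rate_bounds Search interval for the exponential rate `c` (1/kg N);
#'   the sign of `c` is free within it.
#' @return List with `linear` (lm coefficients, rss, aic), `exponential`
#'   (a, b, c, rss, aic), and `preferred` (`"linear"` or `"exponential"`).
#' @examples
#' fits <- relationship_fits(c(31, 241, 462, 677, 899),
#'                           c(18.4, 21.2, 25.4, 32.2, 46.2))
#' fits$preferred
#' @export
relationship_fits <- function(balance, response,
                              rate_bounds = c(-0.02, 0.02)) {
  assert_number(balance, "balance", allow_vector = TRUE)
  assert_number(response, "response", allow_vector = TRUE)
  n <- length(balance)
  if (n < 3L) stop("need at least 3 treatments to fit", call. = FALSE)
  if (length(response) != n) stop("length mismatch", call. = FALSE)
  if (stats::sd(balance) == 0 || stats::sd(response) == 0) {
    stop("degenerate (constant) inputs", call. = FALSE)
  }

  lin <- stats::lm(response ~ balance)
  rss_lin <- sum(stats::residuals(lin)^2)
  aic <- function(rss, k) n * log(max(rss, 1e-12) / n) + 2 * k

  cond_rss <- function(rate) {
    z <- exp(rate * balance)
    if (stats::sd(z) < 1e-12) return(rss_lin)
    f <- stats::lm(response ~ z)
    sum(stats::residuals(f)^2)
  }
  # profile the rate on a grid, then polish with optimize around the best
  grid <- seq(rate_bounds[1], rate_bounds[2], length.out = 201)
  grid <- grid[abs(grid) > 1e-8]
  rss_grid <- vapply(grid, cond_rss, numeric(1))
  best <- grid[which.min(rss_grid)]
  step <- diff(rate_bounds) / 200
  opt <- stats::optimize(cond_rss, c(best - step, best + step))
  rate <- opt$minimum
  z <- exp(rate * balance)
  cf <- stats::coef(stats::lm(response ~ z))
  rss_exp <- opt$objective

  linear <- list(intercept = unname(stats::coef(lin)[1]),
                 slope = unname(stats::coef(lin)[2]),
                 rss = rss_lin, aic = aic(rss_lin, 2))
  exponential <- list(a = unname(cf[1]), b = unname(cf[2]), c = rate,
                      rss = rss_exp, aic = aic(rss_exp, 3))
  list(linear = linear, exponential = exponential,
       preferred = if (exponential$aic < linear$aic) "exponential" else
         "linear")
}
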