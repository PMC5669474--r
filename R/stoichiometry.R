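# Steady-state stoichiometry of mixed-acid fermentation in glucose-limited
# chemostats. At steady state the specific growth rate equals the dilution
# rate D, so the volumetric product formation D*conc and the biomass
# concentration give per-biomass production rates directly.

# carbon atoms per molecule of the measured products and of glucose
PRODUCTS <- c("lactate", "formate", "acetate", "ethanol")
CARBON_PER_PRODUCT <- c(lactate = 3, formate = 1, acetate = 2, ethanol = 2)
CARBON_PER_GLUCOSE <- 6

#' Molar product yield
#'
#' Mol of end-product formed per mol of glucose consumed.
#'
#' @param conc Product concentration (mM) in the culture at steady state.
#' @param glucose_consumed Glucose consumed (mM), i.e. feed minus residual.
#' @return Yield in mol per mol (vectorized).
#' @export
product_yield <- function(conc, glucose_consumed) {
  if (any(glucose_consumed <= 0)) fail_input("glucose_consumed must be > 0")
  if (any(conc < 0)) fail_input("concentrations must be >= 0")
  conc / glucose_consumed
}

#' Specific production
#'
#' Product formed per gram of biomass dry weight (mmol g^-1). Because both
#' concentration and dry weight refer to the same culture volume, the ratio
#' of mM to g/L is mmol per g.
#'
#' @param conc Product concentration (mM).
#' @param dry_weight Biomass dry weight (g per liter), > 0.
#' @return mmol per g dry weight (vectorized).
#' @export
specific_production <- function(conc, dry_weight) {
  if (any(dry_weight <= 0)) fail_input("dry_weight must be > 0")
  if (any(conc < 0)) fail_input("concentrations must be >= 0")
  conc / dry_weight
}

#' Production flux
#'
#' Specific production rate at steady state: D x conc / dW, in
#' mmol h^-1 per g dry weight. Exactly `dilution_rate *
#' specific_production(conc, dry_weight)`.
#'
#' @param conc Product concentration (mM).
#' @param dry_weight Biomass dry weight (g/L), > 0.
#' @param dilution_rate Dilution rate D (h^-1), > 0.
#' @return mmol h^-1 per g dry weight (vectorized).
#' @export
production_flux <- function(conc, dry_weight, dilution_rate) {
  if (any(dilution_rate <= 0)) fail_input("dilution_rate must be > 0")
  dilution_rate * specific_production(conc, dry_weight)
}

#' Carbon balance of mixed-acid fermentation
#'
#' Percent of consumed glucose carbon recovered in the four measured
#' end-products, counting 3 carbons for lactate, 1 for formate and 2 each
#' for acetate and ethanol against 6 per glucose. Biomass carbon, CO2 and
#' minor products are not part of the balance. The pure mixed-acid
#' stoichiometry (1 glucose -> 2 formate + 1 acetate + 1 ethanol) and the
#' homolactic stoichiometry (1 glucose -> 2 lactate) both close at 100%.
#'
#' @param lactate,formate,acetate,ethanol Product concentrations (mM).
#' @param glucose_consumed Glucose consumed (mM), > 0.
#' @return Carbon recovery in percent (vectorized).
#' @export
carbon_balance <- function(lactate, formate, acetate, ethanol, glucose_consumed) {
  if (any(glucose_consumed <= 0)) fail_input("glucose_consumed must be > 0")
  if (any(c(lactate, formate, acetate, ethanol) < 0)) {
    fail_input("concentrations must be >= 0")
  }
  product_carbon <- CARBON_PER_PRODUCT["lactate"] * lactate +
    CARBON_PER_PRODUCT["formate"] * formate +
    CARBON_PER_PRODUCT["acetate"] * acetate +
    CARBON_PER_PRODUCT["ethanol"] * ethanol
  100 * unname(product_carbon) / (CARBON_PER_GLUCOSE * glucose_consumed)
}

#' Signed percent change between growth rates
#'
#' Change from high to low growth rate expressed relative to the larger of
#' the two values; positive means an increase at low growth. This
#' normalization treats increases and decreases symmetrically
#' (antisymmetric under swapping the arguments).
#'
#' @param y_high Value at high growth rate.
#' @param y_low Value at low growth rate.
#' @return Signed percent change (vectorized).
#' @export
percent_change <- function(y_high, y_low) {
  denom <- pmax(y_high, y_low)
  if (any(denom <= 0)) fail_input("percent_change needs a positive larger value")
  100 * (y_low - y_high) / denom
}

#' Per-sample metabolic phenotype profile
#'
#' Derives, for every steady-state observation, the molar yields, specific
#' productions, production fluxes and the carbon balance from the measured
#' concentrations.
#'
#' @param obs Metabolite table as returned by [read_metabolite_table()].
#' @return The input with derived columns appended: `glucose_consumed`,
#'   `<product>_yield`, `<product>_mmol_g`, `<product>_flux`, and
#'   `carbon_balance`.
#' @export
phenotype_profile <- function(obs) {
  if (nrow(obs) == 0) fail_input("empty metabolite table")
  if (!"residual_glucose" %in% names(obs)) obs$residual_glucose <- 0
  out <- obs
  out$glucose_consumed <- obs$glucose_feed - obs$residual_glucose
  for (p in PRODUCTS) {
    out[[paste0(p, "_yield")]] <- product_yield(obs[[p]], out$glucose_consumed)
    out[[paste0(p, "_mmol_g")]] <- specific_production(obs[[p]], obs$dry_weight)
    out[[paste0(p, "_flux")]] <- production_flux(
      obs[[p]], obs$dry_weight, obs$dilution_rate
    )
  }
  out$carbon_balance <- carbon_balance(
    obs$lactate, obs$formate, obs$acetate, obs$ethanol, out$glucose_consumed
  )
  out
}

#' Replicate summary of chemostat phenotypes
#'
#' Groups observations by strain and dilution rate and reports the mean and
#' standard deviation of dry weight, concentrations, specific productions,
#' fluxes and carbon balance. All derived quantities are computed per
#' replicate first and then averaged.
#'
#' @param obs Metabolite table (one row per replicate).
#' @return Data frame with one row per strain x dilution-rate group;
#'   `<quantity>` columns hold means, `<quantity>_sd` standard deviations
#'   (`NA` for a single replicate), and `n` the replicate count.
#' @export
summarize_phenotypes <- function(obs) {
  prof <- phenotype_profile(obs)
  key <- interaction(prof$strain, prof$dilution_rate, drop = TRUE)
  vars <- c(
    "dry_weight",
    PRODUCTS,
    paste0(PRODUCTS, "_yield"),
    paste0(PRODUCTS, "_mmol_g"),
    paste0(PRODUCTS, "_flux"),
    "carbon_balance"
  )
  groups <- split(prof, key)
  rows <- lapply(groups, function(g) {
    res <- data.frame(
      strain = g$strain[1],
      dilution_rate = g$dilution_rate[1],
      n = nrow(g),
      stringsAsFactors = FALSE
    )
    for (v in vars) {
      res[[v]] <- mean(g[[v]])
      res[[paste0(v, "_sd")]] <- stats::sd(g[[v]])
    }
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strain, -out$dilution_rate), , drop = FALSE]
  rownames(out) <- NULL
  out
}
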