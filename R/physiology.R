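# Derived specific rates: ATP (substrate-level + oxidative phosphorylation),
# growth, CO2, NADPH, NADH, and batch carbon balances.

flux0 <- function(fluxes, id) if (id %in% names(fluxes)) fluxes[[id]] else 0

#' Specific ATP production rate
#'
#' Oxidative phosphorylation converts the proton flux pumped by Nuo
#' (H+/e- = 2), Cyo (2) and Cyd (1) into ATP at H+/ATP = 3; with respiratory
#' fluxes in 2-electron units, `OP = (4 v_Nuo + 4 v_Cyo + 2 v_Cyd) / 3`.
#' Substrate-level terms add the lumped glycolytic payoff (L_Emp), Pyk,
#' acetate kinase (PTACK) and the succinyl-CoA step (aKGDH), minus the
#' ATP-consuming reactions Glk, Pfk, Pps, Pck and Acs.
#'
#' @param fluxes a named flux vector (mmol/gDW/h).
#' @param params unused; kept for interface symmetry.
#' @return list with `v_ATP`, `OP`, and a named `breakdown` of every term.
#' @export
atp_rate <- function(fluxes, params = NULL) {
  op <- (4 * flux0(fluxes, "Nuo") + 4 * flux0(fluxes, "Cyo") +
           2 * flux0(fluxes, "Cyd")) / 3
  breakdown <- c(
    OP     = op,
    L_Emp  = flux0(fluxes, "L_Emp"),
    Pyk    = flux0(fluxes, "Pyk"),
    PTACK  = flux0(fluxes, "PTACK"),
    aKGDH  = flux0(fluxes, "aKGDH"),
    Glk    = -flux0(fluxes, "Glk"),
    Pfk    = -flux0(fluxes, "Pfk"),
    Pps    = -flux0(fluxes, "Pps"),
    Pck    = -flux0(fluxes, "Pck"),
    Acs    = -flux0(fluxes, "Acs")
  )
  list(v_ATP = sum(breakdown), OP = op, breakdown = breakdown)
}

#' Specific growth rate from the ATP production rate
#'
#' Growth is linearly coupled to ATP production, `mu = k_ATP * v_ATP`,
#' floored at zero (no death term).
#'
#' @param v_atp specific ATP production rate (mmol/gDW/h).
#' @param params a `parameter_set` providing `k_ATP` (gDW/mmol).
#' @return specific growth rate (1/h).
#' @export
growth_rate <- function(v_atp, params) {
  max(params[["k_ATP"]] * v_atp, 0)
}

#' Specific CO2 production rate
#'
#' `v_CO2 = v_PGDH + v_PDH + v_ICDH + v_aKGDH + v_Mez + v_Pck - v_Ppc`;
#' negative values indicate net carboxylation.
#'
#' @param fluxes a named flux vector.
#' @return specific CO2 production rate (mmol/gDW/h).
#' @export
co2_rate <- function(fluxes) {
  flux0(fluxes, "PGDH") + flux0(fluxes, "PDH") + flux0(fluxes, "ICDH") +
    flux0(fluxes, "aKGDH") + flux0(fluxes, "Mez") + flux0(fluxes, "Pck") -
    flux0(fluxes, "Ppc")
}

#' Specific NADPH production rate
#'
#' `v_NADPH = v_G6PDH + v_PGDH + v_ICDH + v_Mez`.  Reported as a diagnostic
#' only: the printed balance has no consumption term, so NADPH does not
#' enter the ODE state.
#'
#' @param fluxes a named flux vector.
#' @return specific NADPH production rate (mmol/gDW/h).
#' @export
nadph_rate <- function(fluxes) {
  flux0(fluxes, "G6PDH") + flux0(fluxes, "PGDH") + flux0(fluxes, "ICDH") +
    flux0(fluxes, "Mez")
}

#' Specific net NADH production rate with source breakdown
#'
#' `v_NADH = v_L_Emp + v_PDH + v_aKGDH + v_MDH - v_LDH - v_ALDH - v_ADH -
#' v_Nuo - v_Ndh`.  The breakdown groups glycolysis, PDH and TCA production
#' against consumption by lactate formation, ethanol formation (ALDH + ADH),
#' respiration (Nuo + Ndh) and the reductive TCA arm (MDH when negative).
#'
#' @param fluxes a named flux vector.
#' @return list with `v_NADH` and a named `breakdown`.
#' @export
nadh_rate <- function(fluxes) {
  terms <- c(
    L_Emp = flux0(fluxes, "L_Emp"),
    PDH   = flux0(fluxes, "PDH"),
    aKGDH = flux0(fluxes, "aKGDH"),
    MDH   = flux0(fluxes, "MDH"),
    LDH   = -flux0(fluxes, "LDH"),
    ALDH  = -flux0(fluxes, "ALDH"),
    ADH   = -flux0(fluxes, "ADH"),
    Nuo   = -flux0(fluxes, "Nuo"),
    Ndh   = -flux0(fluxes, "Ndh")
  )
  mdh <- terms[["MDH"]]
  breakdown <- c(
    glycolysis    = terms[["L_Emp"]],
    PDH           = terms[["PDH"]],
    TCA           = terms[["aKGDH"]] + max(mdh, 0),
    lactate       = terms[["LDH"]],
    ethanol       = terms[["ALDH"]] + terms[["ADH"]],
    respiration   = terms[["Nuo"]] + terms[["Ndh"]],
    reductive_TCA = min(mdh, 0)
  )
  list(v_NADH = sum(terms), breakdown = breakdown)
}

#' Carbon balance of a completed batch trajectory
#'
#' Apportions the carbon of the consumed glucose to the excreted products
#' (acetate, lactate, formate, ethanol, succinate), CO2, biomass, and the
#' residual held in intracellular metabolites, as fractions of consumed
#' glucose carbon.  CO2 and biomass carbon come from the cumulative columns
#' integrated alongside the state (exact to solver tolerance); for
#' trajectories lacking them, trapezoidal quadrature of the specific CO2
#' rate and the nominal biomass carbon content `c_X` are used instead.
#'
#' @param trajectory a `batch_trajectory` from [simulate_batch()].
#' @param network the `metabolic_network` used for the simulation.
#' @return named numeric vector of fractions (`acetate`, `lactate`,
#'   `formate`, `ethanol`, `succinate`, `CO2`, `biomass`, `residual`)
#'   summing to ~1.
#' @export
carbon_balance <- function(trajectory, network) {
  ts <- trajectory$time_series
  if (nrow(ts) < 2L) {
    out <- rep(0, 8)
    names(out) <- c("acetate", "lactate", "formate", "ethanol", "succinate",
                    "CO2", "biomass", "residual")
    return(out)
  }
  if (!isTRUE(trajectory$depleted))
    warning("trajectory did not reach glucose depletion; ",
            "balance computed on the consumed fraction")
  first <- ts[1L, ]; last <- ts[nrow(ts), ]
  sp <- network$species
  cmol <- function(id, delta_gl) {
    s <- sp[[id]]
    delta_gl / s$mw * s$carbon  # g/l -> mol C basis (per liter, x1000 cancels)
  }
  consumed_c <- cmol("GLCx", first$GLCx - last$GLCx)
  if (consumed_c <= 0) stop("no glucose consumed over the trajectory")
  prod_c <- c(
    acetate   = cmol("ACEx", last$ACEx - first$ACEx),
    lactate   = cmol("LACx", last$LACx - first$LACx),
    formate   = cmol("FORx", last$FORx - first$FORx),
    ethanol   = cmol("ETHx", last$ETHx - first$ETHx),
    succinate = cmol("SUCx", last$SUCx - first$SUCx)
  )
  # CO2: integrate X * v_CO2 (mmol/l/h) over time -> mmol C/l -> mol/l
  co2_c <- if (!is.null(ts$CO2cum)) (last$CO2cum - first$CO2cum) / 1000 else {
    integrand <- ts$X * ts$v_CO2 / 1000
    sum(diff(ts$time) *
          (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2)
  }
  # biomass carbon: the integrated precursor drain when available (exact),
  # otherwise the nominal carbon content of the biomass formed
  biomass_c <- if (!is.null(ts$BMCcum)) (last$BMCcum - first$BMCcum) / 1000
  else (last$X - first$X) * trajectory$params[["c_X"]] / 12.011
  # residual carbon accumulated in intracellular metabolites (mmol/gDW * gDW/l)
  cyt <- names(sp)[vapply(sp, function(s)
    identical(s$compartment, "cytoplasm"), TRUE)]
  res_c <- 0
  for (id in cyt) {
    cnum <- sp[[id]]$carbon
    res_c <- res_c + (last[[id]] * last$X - first[[id]] * first$X) * cnum / 1000
  }
  out <- c(prod_c, CO2 = co2_c, biomass = biomass_c, residual = res_c) / consumed_c
  out
}
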