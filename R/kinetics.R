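# Rate-law registry and flux evaluation.
#
# Forms:
#   mm         irreversible multiplicative Michaelis-Menten,
#              v = vmax * prod_s S/(Ks+S) * effector factors
#   rev_mm     mass-action-ratio MM, v = vmax * (S/Ks - P/(Ks*Keq)) /
#              (1 + S/Ks + P/Kp)
#   two_way_mm difference of two irreversible MM terms (used for MDH, where
#              the NADH/NAD+ state decides the net direction)
# Effectors: activation (1 + beta*A/(Ka+A)), inhibition 1/(1 + I/Ki), and
# redox_activation R^h/(K^h + R^h) on the NADH/NAD+ ratio.  All factors are
# 1 when the effector is absent, so removing an effector never introduces a
# discontinuity.

compile_rate <- function(rx, params, idx) {
  r <- rx$rate
  pv <- function(sym) {
    val <- params[[sym]]
    if (is.null(val) || is.na(val)) stop("missing parameter: ", sym)
    val
  }
  make_effectors <- function(effs) {
    if (is.null(effs)) return(NULL)
    lapply(effs, function(e) {
      if (identical(e$type, "inhibition")) {
        i <- idx[[e$species]]; ki <- pv(e$ki)
        function(cc) 1 / (1 + cc[i] / ki)
      } else if (identical(e$type, "activation")) {
        i <- idx[[e$species]]; ka <- pv(e$ka); beta <- pv(e$beta)
        function(cc) 1 + beta * cc[i] / (ka + cc[i])
      } else if (identical(e$type, "redox_activation")) {
        inadh <- idx[["NADH"]]; inad <- idx[["NADp"]]
        k <- pv(e$k); h <- pv(e$hill)
        function(cc) {
          ratio <- cc[inadh] / max(cc[inad], 1e-12)
          ratio^h / (k^h + ratio^h)
        }
      } else stop("unknown effector type: ", e$type)
    })
  }

  if (identical(r$form, "mm")) {
    vmax <- pv(r$vmax)
    si <- vapply(r$substrates, function(s) idx[[s$species]], 0L)
    km <- vapply(r$substrates, function(s) pv(s$km), 0)
    # optional per-substrate Hill exponent (numeric literal, default 1)
    hh <- vapply(r$substrates, function(s) as.numeric(s$hill %||% 1), 0)
    effs <- make_effectors(r$effectors)
    if (all(hh == 1)) {
      if (is.null(effs)) {
        function(cc) vmax * prod(cc[si] / (km + cc[si]))
      } else {
        function(cc) {
          v <- vmax * prod(cc[si] / (km + cc[si]))
          for (f in effs) v <- v * f(cc)
          v
        }
      }
    } else {
      function(cc) {
        s <- cc[si]^hh
        v <- vmax * prod(s / (km^hh + s))
        if (!is.null(effs)) for (f in effs) v <- v * f(cc)
        v
      }
    }
  } else if (identical(r$form, "rev_mm")) {
    vmax <- pv(r$vmax); keq <- pv(r$keq)
    is <- idx[[r$substrate$species]]; ks <- pv(r$substrate$km)
    ip <- idx[[r$product$species]];   kp <- pv(r$product$km)
    function(cc) {
      s <- cc[is]; p <- cc[ip]
      vmax * (s / ks - p / (ks * keq)) / (1 + s / ks + p / kp)
    }
  } else if (identical(r$form, "two_way_mm")) {
    vf <- pv(r$forward$vmax)
    fi <- vapply(r$forward$substrates, function(s) idx[[s$species]], 0L)
    fk <- vapply(r$forward$substrates, function(s) pv(s$km), 0)
    vr <- pv(r$reverse$vmax)
    ri <- vapply(r$reverse$substrates, function(s) idx[[s$species]], 0L)
    rk <- vapply(r$reverse$substrates, function(s) pv(s$km), 0)
    function(cc) {
      vf * prod(cc[fi] / (fk + cc[fi])) - vr * prod(cc[ri] / (rk + cc[ri]))
    }
  } else if (identical(r$form, "pts")) {
    # lumped phosphotransferase uptake: driven by the PEP/PYR phosphorylation
    # potential, saturable in extracellular glucose
    vmax <- pv(r$vmax)
    ig <- idx[[r$glucose$species]]; kg <- pv(r$glucose$km)
    ipep <- idx[["PEP"]]; ipyr <- idx[["PYR"]]
    kr <- pv(r$k_ratio)
    function(cc) {
      ratio <- cc[ipep] / max(cc[ipyr], 1e-9)
      vmax * cc[ig] / (kg + cc[ig]) * ratio / (kr + ratio)
    }
  } else if (identical(r$form, "mass_action")) {
    k <- pv(r$vmax)
    si <- vapply(r$substrates, function(s) idx[[s$species]], 0L)
    function(cc) k * prod(cc[si])
  } else stop("unknown rate-law form: ", r$form)
}

#' Compile a network + parameter set into a fast model object
#'
#' Resolves every rate-law symbol against the parameter set once and builds
#' per-reaction closures over an indexed concentration vector, so that flux
#' evaluation inside the ODE right-hand side costs no name lookups.
#'
#' @param network a `metabolic_network`.
#' @param params a `parameter_set` (possibly knockout-modified).
#' @return an object of class `compiled_model`.
#' @export
compile_model <- function(network, params) {
  sp <- network$species
  ids <- network$species_ids
  partners <- unlist(lapply(sp, function(s) s$partner), use.names = FALSE)
  conc_names <- c(ids, partners)
  idx <- seq_along(conc_names); names(idx) <- conc_names

  comp <- vapply(sp, `[[`, "", "compartment")
  state_ids <- ids[comp %in% c("extracellular", "cytoplasm", "pool")]

  S_full <- stoichiometry_matrix(network)[conc_names, , drop = FALSE]
  rates <- lapply(network$reactions, compile_rate, params = params, idx = idx)

  pool_specs <- sp[comp == "pool"]
  pool_totals <- vapply(pool_specs, function(s) params[[s$total]], 0)
  names(pool_totals) <- vapply(pool_specs, `[[`, "", "id")
  pool_partner <- vapply(pool_specs, `[[`, "", "partner")
  names(pool_partner) <- names(pool_totals)

  base_factors <- rep(1, length(network$reactions))
  names(base_factors) <- network$reaction_ids

  structure(list(
    network = network, params = params,
    conc_names = conc_names, idx = idx,
    state_ids = state_ids,
    compartment = comp,
    S = S_full,
    rates = rates,
    pool_totals = pool_totals,
    pool_partner = pool_partner,
    fnr_scale = attr(params, "fnr_scale") %||% 1,
    arca_scale = attr(params, "arca_scale") %||% 1,
    mw = vapply(sp, function(s) as.numeric(s$mw %||% NA_real_), 0),
    carbon = vapply(sp, function(s) as.numeric(s$carbon %||% 0), 0)
  ), class = "compiled_model")
}

# Full concentration vector (states + pool partners + boundary values) from
# a named state vector and the boundary oxygen concentration.
full_concentrations <- function(model, state, o2 = 0) {
  cc <- numeric(length(model$conc_names))
  names(cc) <- model$conc_names
  cc[names(state)] <- state
  for (pm in names(model$pool_totals)) {
    cc[model$pool_partner[[pm]]] <- model$pool_totals[[pm]] - cc[[pm]]
  }
  if ("O2" %in% model$conc_names) cc[["O2"]] <- o2
  cc
}

# Core evaluator on a pre-assembled concentration vector; reg_f is the
# per-reaction regulation factor vector.
eval_fluxes_cc <- function(model, cc, reg_f) {
  # stiff-solver trial steps may probe slightly negative concentrations;
  # values are clamped at zero for rate evaluation and only a meaningful
  # undershoot (beyond -1e-6) is treated as an integrator failure
  neg <- cc < -1e-6
  if (any(neg))
    stop("negative concentration for ",
         paste(model$conc_names[neg], collapse = ", "),
         " (integrator failure upstream)")
  cc[cc < 0] <- 0
  n <- length(model$rates)
  v <- numeric(n)
  for (j in seq_len(n)) v[j] <- reg_f[j] * model$rates[[j]](cc)
  names(v) <- model$network$reaction_ids
  v
}

#' Evaluate all specific reaction rates
#'
#' Computes the flux through every declared reaction (mmol/gDW/h) from the
#' current concentrations, with each maximal rate scaled by the
#' transcription-factor regulation factors for the supplied redox
#' environment.  Respiratory fluxes are expressed per 2-electron transfer.
#'
#' @param state named numeric vector of tracked concentrations
#'   (extracellular in g/l, intracellular and pool members in mmol/gDW).
#' @param env a `redox_environment` (see [redox_environment()]), or a DO
#'   percentage from which one is built using the state's Q value.
#' @param network a `metabolic_network`.
#' @param params a `parameter_set`.
#' @return named flux vector of class `flux_vector`.
#' @export
evaluate_fluxes <- function(state, env, network, params) {
  model <- compile_model(network, params)
  if (is.numeric(env))
    env <- redox_environment(env, q = state[["Q"]], params = params,
                             fnr_scale = model$fnr_scale,
                             arca_scale = model$arca_scale)
  reg_f <- regulation_factors(network, params, env$TF_Fnr, env$TF_ArcA)
  cc <- full_concentrations(model, state, o2 = env$O2_cyt)
  v <- eval_fluxes_cc(model, cc, reg_f)
  structure(v, class = c("flux_vector", "numeric"))
}

#' Specific oxygen uptake rate from respiratory fluxes
#'
#' The terminal oxidases Cyo and Cyd are expressed per 2-electron (one
#' quinol) transfer; one O2 molecule accepts four electrons, so
#' `qOUR = (v_Cyo + v_Cyd) / 2` in mmol O2/gDW/h.
#'
#' @param fluxes a named flux vector containing `Cyo` and `Cyd`.
#' @return specific oxygen uptake rate (mmol O2/gDW/h).
#' @export
respiratory_o2_consumption <- function(fluxes) {
  unname(0.5 * (fluxes[["Cyo"]] + fluxes[["Cyd"]]))
}
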