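#' Convert a dissolved-oxygen setpoint to cytoplasmic oxygen concentration
#'
#' The dissolved-oxygen (DO) level is expressed as percent of air saturation
#' at 37 C; the medium concentration is `DO/100 * DO2_star` and the
#' cytoplasmic concentration is scaled down by `k_O2 <= 1` (oxygen inside
#' the cell is at most the medium level).
#'
#' @param do_percent DO level in percent of air saturation, in \[0, 100\].
#' @param params a `parameter_set` providing `k_O2` and `DO2_star`.
#' @return cytoplasmic oxygen concentration (mM), same length as
#'   `do_percent`.
#' @export
do_percent_to_o2 <- function(do_percent, params) {
  if (any(!is.finite(do_percent)) || any(do_percent < 0 | do_percent > 100))
    stop("DO level must lie in [0, 100] percent of air saturation")
  params[["k_O2"]] * (do_percent / 100) * params[["DO2_star"]]
}

# Hill activity with negative coefficient n, evaluated through the
# singularity-free equivalent K^|n| / (K^|n| + x^|n|); exact at x = 0.
hill_negative <- function(x, K, n) {
  if (any(x < 0)) stop("Hill ligand concentration must be non-negative")
  m <- abs(n)
  K^m / (K^m + x^m)
}

#' Fnr activity as a function of cytoplasmic oxygen
#'
#' Hill function with a negative coefficient: activity is 1 in the absence
#' of oxygen, 0.5 at `K_Fnr`, and decreases monotonically towards 0 as
#' oxygen rises.  Implemented through the equivalent form
#' `K^|n| / (K^|n| + O2^|n|)`, which avoids the `0^negative` singularity of
#' the literal expression.
#'
#' @param o2 cytoplasmic oxygen concentration (mM), non-negative.
#' @param params a `parameter_set` providing `K_Fnr` and `n_hill`.
#' @return activity in \[0, 1\].
#' @export
fnr_activity <- function(o2, params) {
  hill_negative(o2, params[["K_Fnr"]], params[["n_hill"]])
}

#' ArcA activity as a function of the oxidized quinone concentration
#'
#' Oxidized quinone inhibits ArcB autophosphorylation, so ArcA activity is a
#' decreasing Hill function of \[Q\]: 1 when the pool is fully reduced, 0.5
#' at `K_ArcA`.  The ArcB phosphorelay is treated as quasi-steady, making
#' the activity an algebraic function of the instantaneous quinone state.
#'
#' @param q oxidized quinone concentration (mmol/gDW), non-negative.
#' @param params a `parameter_set` providing `K_ArcA` and `n_hill`.
#' @return activity in \[0, 1\].
#' @export
arca_activity <- function(q, params) {
  hill_negative(q, params[["K_ArcA"]], params[["n_hill"]])
}

#' Transcription-factor scaling factors for every reaction
#'
#' Each regulation edge multiplies the reaction's maximal rate: an
#' activation edge by `(1 + a * TF)`, a repression edge by `1 / (1 + r * TF)`,
#' with per-edge strengths `a`, `r >= 0` taken from the parameter set.
#' Unregulated reactions keep factor 1, as do all reactions when both
#' activities are zero.
#'
#' @param network a `metabolic_network`.
#' @param params a `parameter_set`.
#' @param tf_fnr,tf_arca activities in \[0, 1\].
#' @return named numeric vector of factors, one per reaction.
#' @export
regulation_factors <- function(network, params, tf_fnr, tf_arca) {
  f <- rep(1, length(network$reactions))
  names(f) <- network$reaction_ids
  act <- c(Fnr = tf_fnr, ArcA = tf_arca)
  for (e in network$regulation) {
    s <- params[[e$strength]]
    tf <- act[[e$tf]]
    f[[e$reaction]] <- f[[e$reaction]] *
      if (identical(e$sign, "activation")) 1 + s * tf else 1 / (1 + s * tf)
  }
  f
}

#' Effective maximal rate of one reaction under a regulatory state
#'
#' @param reaction a reaction id present in `network`.
#' @param network a `metabolic_network`.
#' @param params a `parameter_set`.
#' @param tf_fnr,tf_arca transcription-factor activities in \[0, 1\].
#' @return effective vmax (mmol/gDW/h).
#' @export
modulate_vmax <- function(reaction, network, params, tf_fnr = 0, tf_arca = 0) {
  rx <- network$reactions[[reaction]]
  if (is.null(rx)) stop("unknown reaction: ", reaction)
  base <- if (!is.null(rx$rate$vmax)) params[[rx$rate$vmax]]
          else params[[rx$rate$forward$vmax]]
  f <- regulation_factors(network, params, tf_fnr, tf_arca)
  unname(base * f[[reaction]])
}

#' Classify a DO level into the four oxygen-condition categories
#'
#' Category I is the anaerobic endpoint (DO = 0), II the strongly
#' micro-aerobic regime (0 < DO < 7) where both Fnr and ArcA are active,
#' III the micro-aerobic regime (7 <= DO < 20) where ArcA is primarily
#' active, and IV the aerobic regime (DO >= 20) where neither factor is
#' active.  The boundaries label conditions for reporting only; no model
#' behavior switches on them.
#'
#' @param do_percent DO level(s) in \[0, 100\].
#' @return character vector of "I", "II", "III", "IV".
#' @export
classify_condition <- function(do_percent) {
  if (any(do_percent < 0 | do_percent > 100))
    stop("DO level must lie in [0, 100]")
  ifelse(do_percent == 0, "I",
    ifelse(do_percent < 7, "II",
      ifelse(do_percent < 20, "III", "IV")))
}

#' Redox environment at a DO setpoint
#'
#' Bundles the DO level, medium and cytoplasmic oxygen concentrations, the
#' transcription-factor activities and the condition category for a given
#' oxidized-quinone concentration.
#'
#' @param do_percent DO level in \[0, 100\].
#' @param q oxidized quinone concentration (mmol/gDW).
#' @param params a `parameter_set`.
#' @param fnr_scale,arca_scale knockout multipliers (0 silences the factor).
#' @return a list of class `redox_environment`.
#' @export
redox_environment <- function(do_percent, q, params,
                              fnr_scale = 1, arca_scale = 1) {
  o2 <- do_percent_to_o2(do_percent, params)
  structure(list(
    DO_percent = do_percent,
    DO_conc    = (do_percent / 100) * params[["DO2_star"]],
    O2_cyt     = o2,
    Q          = q,
    TF_Fnr     = fnr_scale * fnr_activity(o2, params),
    TF_ArcA    = arca_scale * arca_activity(q, params),
    condition  = classify_condition(do_percent)
  ), class = "redox_environment")
}
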