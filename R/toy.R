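# Synthetic three-metabolite fixture with a conserved cofactor pair and a
# closed-form steady state; the gate for integrator and rate-law refactors.

#' Build the toy linear-pathway model
#'
#' A boundary substrate S feeds a three-step pathway
#' `S -> A -> B -> P` in which the first step is transcription-factor
#' regulated (an activation edge on the oxygen-sensing factor) and the two
#' downstream steps exchange a conserved cofactor pair (C / CH): step 2
#' reduces the cofactor (`A + C -> B + CH`), step 3 reoxidizes it
#' (`B + CH -> P + C`).  All steps are mass action.  The steady state is
#' available in closed form (see [toy_steady_state()]) and is unique for
#' positive dials.
#'
#' @param k1,k2,k3 rate constants of the three steps (1/h; k2, k3 per
#'   concentration unit).
#' @param S_fix fixed boundary substrate concentration.
#' @param C_total conserved cofactor pool total.
#' @param a_TF activation strength of the regulation edge on step 1.
#' @param stiffness multiplier applied to k2 and k3 to stiffen the cofactor
#'   cycling relative to the pathway flux.
#' @return list with `network`, `params` (a `parameter_set`), and the
#'   initial state used by the closed form.
#' @export
make_toy <- function(k1 = 0.4, k2 = 5, k3 = 4, S_fix = 1, C_total = 1,
                     a_TF = 1.5, stiffness = 1) {
  if (any(c(k1, k2, k3, S_fix, C_total, stiffness) <= 0) || a_TF < 0)
    stop("toy dials must be positive (a_TF non-negative)")
  if (stiffness > 1e6)
    stop("stiffness dial out of documented range (<= 1e6)")
  network <- structure(list(
    name = "toy_linear",
    species = list(
      S  = list(id = "S", compartment = "boundary", carbon = 1, fixed = "S_fix"),
      P  = list(id = "P", compartment = "boundary", carbon = 1),
      A  = list(id = "A", compartment = "cytoplasm", carbon = 1, init = 0.1),
      B  = list(id = "B", compartment = "cytoplasm", carbon = 1, init = 0.1),
      CH = list(id = "CH", compartment = "pool", carbon = 0, pool = "C",
                partner = "C", total = "C_total", init = 0.4)
    ),
    reactions = list(
      v1 = list(id = "v1", gene = "g1",
                stoichiometry = list(S = -1, A = 1),
                rate = list(form = "mass_action", vmax = "k1",
                            substrates = list(list(species = "S")))),
      v2 = list(id = "v2", gene = "g2",
                stoichiometry = list(A = -1, C = -1, B = 1, CH = 1),
                rate = list(form = "mass_action", vmax = "k2",
                            substrates = list(list(species = "A"),
                                              list(species = "C")))),
      v3 = list(id = "v3", gene = "g3",
                stoichiometry = list(B = -1, CH = -1, P = 1, C = 1),
                rate = list(form = "mass_action", vmax = "k3",
                            substrates = list(list(species = "B"),
                                              list(species = "CH"))))
    ),
    regulation = list(
      list(tf = "Fnr", gene = "g1", reaction = "v1",
           sign = "activation", strength = "a_TF")
    )
  ), class = "metabolic_network")
  network$species_ids <- names(network$species)
  network$reaction_ids <- names(network$reactions)

  params <- load_parameters(c(
    k1 = k1, k2 = k2 * stiffness, k3 = k3 * stiffness,
    S_fix = S_fix, C_total = C_total, a_TF = a_TF,
    # oxygen machinery so the regulated step responds to a DO dial
    K_Fnr = 0.0037, n_hill = -4, k_O2 = 0.5, DO2_star = 0.21))
  list(network = network, params = params,
       y0 = c(A = 0.1, B = 0.1, CH = 0.4))
}

#' Closed-form steady state of the toy model
#'
#' At steady state the three fluxes are equal.  With
#' `v1 = k1 (1 + a_TF * TF) * S_fix` and the invariant `CH - B = c0` fixed
#' by the initial condition, the cofactor partition solves
#' `k3 * (CH - c0) * CH = v1`, giving
#' `CH* = (c0 + sqrt(c0^2 + 4 v1 / k3)) / 2`, `B* = CH* - c0`,
#' `C* = C_total - CH*`, and `A* = v1 / (k2 * C*)`.
#'
#' @param toy the list returned by [make_toy()].
#' @param tf transcription-factor activity applied to step 1, in \[0, 1\].
#' @return named vector `A`, `B`, `CH` plus the steady flux `v`.
#' @export
toy_steady_state <- function(toy, tf = 1) {
  p <- toy$params
  v1 <- p[["k1"]] * (1 + p[["a_TF"]] * tf) * p[["S_fix"]]
  c0 <- toy$y0[["CH"]] - toy$y0[["B"]]
  ch <- (c0 + sqrt(c0^2 + 4 * v1 / p[["k3"]])) / 2
  if (ch >= p[["C_total"]])
    stop("no positive steady state: cofactor pool fully reduced; ",
         "reduce k1/S_fix or enlarge C_total")
  c(A = unname(v1 / (p[["k2"]] * (p[["C_total"]] - ch))),
    B = unname(ch - c0), CH = unname(ch), v = unname(v1))
}
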