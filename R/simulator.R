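# Batch-culture ODE assembly and integration.
#
# State layout: extracellular species (g/l), biomass X (gDW/l), intracellular
# metabolites (mmol/gDW, with growth dilution -mu*C), tracked pool members
# (NADH, Q; pool totals are per-gDW constants, so no dilution), and a
# cumulative CO2 column (mmol/l) integrated alongside for exact carbon
# balances.  Dissolved oxygen is a controlled boundary condition (algebraic,
# no mass-transfer ODE); a DO switch restarts the integration at the
# discontinuity.

#' Define a batch cultivation protocol
#'
#' @param glc0 initial glucose (g/l).
#' @param x0 initial biomass (gDW/l).
#' @param do DO schedule: a single percentage held constant, or a
#'   two-column `data.frame(time, do)` of setpoints applied stepwise from
#'   each `time` onward (first row must start at 0).
#' @param strain a `strain_spec` or shortcut name ("WT", "fnr", "arcA",
#'   "pfl").
#' @param glc_threshold glucose-depletion threshold (g/l) ending the batch.
#' @param t_max maximum simulated time (h).
#' @return an object of class `cultivation_protocol`.
#' @export
cultivation_protocol <- function(glc0 = 10, x0 = 0.035, do = 40,
                                 strain = "WT", glc_threshold = 0.01,
                                 t_max = 60) {
  if (is.numeric(do) && length(do) == 1L)
    do <- data.frame(time = 0, do = do)
  stopifnot(is.data.frame(do), all(c("time", "do") %in% names(do)),
            do$time[1] == 0, !is.unsorted(do$time, strictly = TRUE),
            all(do$do >= 0 & do$do <= 100),
            glc_threshold > 0, t_max > 0, glc0 >= 0, x0 > 0)
  if (is.character(strain)) strain <- strain_spec(strain)
  structure(list(glc0 = glc0, x0 = x0, do = do, strain = strain,
                 glc_threshold = glc_threshold, t_max = t_max),
            class = "cultivation_protocol")
}

# Regulation factors split into a constant Fnr part (DO fixed per segment)
# and the ArcA edges applied per step from the quinone state.
split_regulation <- function(network, params, tf_fnr) {
  n <- length(network$reactions)
  fnr_fac <- rep(1, n)
  names(fnr_fac) <- network$reaction_ids
  arca_edges <- list()
  for (e in network$regulation) {
    s <- params[[e$strength]]
    if (identical(e$tf, "Fnr")) {
      fnr_fac[[e$reaction]] <- fnr_fac[[e$reaction]] *
        if (identical(e$sign, "activation")) 1 + s * tf_fnr
        else 1 / (1 + s * tf_fnr)
    } else {
      arca_edges[[length(arca_edges) + 1L]] <-
        list(j = match(e$reaction, network$reaction_ids),
             act = identical(e$sign, "activation"), s = s)
    }
  }
  list(fnr_fac = fnr_fac, arca_edges = arca_edges)
}

#' Simulate a batch fermentation
#'
#' Integrates the batch ODE system under the protocol's DO schedule with a
#' stiff-capable adaptive solver (`deSolve::lsodar`), locating the
#' glucose-depletion event by root finding.  The run is fully deterministic.
#'
#' @param protocol a `cultivation_protocol`.
#' @param network a `metabolic_network` (default: the shipped E. coli
#'   network).
#' @param params a `parameter_set` (default: the shipped refit set).
#' @param rtol,atol solver tolerances.
#' @param dt_out output sampling interval (h); the depletion time itself is
#'   always included as the final row.
#' @return an object of class `batch_trajectory`: list with `time_series`
#'   (data frame of states, TF activities, fluxes `v_*` and derived rates),
#'   `t_dep`, `depleted`, `protocol`, `params`, and solver settings.
#' @export
simulate_batch <- function(protocol, network = ecoli_network(),
                           params = default_parameters(),
                           rtol = 1e-8, atol = 1e-10, dt_out = 0.05) {
  stopifnot(inherits(protocol, "cultivation_protocol"))
  ko <- apply_knockout(network, params, protocol$strain)
  network <- ko$network; params <- ko$params
  model <- compile_model(network, params)

  comp <- model$compartment
  ext_ids <- names(comp)[comp == "extracellular"]
  cyt_ids <- names(comp)[comp == "cytoplasm"]
  pool_ids <- names(comp)[comp == "pool"]
  state_ids <- c(ext_ids, "X", cyt_ids, pool_ids, "CO2cum", "BMCcum")

  y0 <- numeric(length(state_ids)); names(y0) <- state_ids
  for (id in c(ext_ids, cyt_ids, pool_ids))
    y0[[id]] <- network$species[[id]]$init %||% 0
  y0[["GLCx"]] <- protocol$glc0
  y0[["X"]] <- protocol$x0
  y0[["CO2cum"]] <- 0
  y0[["BMCcum"]] <- 0

  S <- model$S
  S_ext <- S[ext_ids, , drop = FALSE]
  S_cyt <- S[cyt_ids, , drop = FALSE]
  S_pool <- S[pool_ids, , drop = FALSE]
  ext_w <- model$mw[ext_ids] / 1000

  rxid <- network$reaction_ids
  j_of <- function(id) match(id, rxid)
  j_nuo <- j_of("Nuo"); j_cyo <- j_of("Cyo"); j_cyd <- j_of("Cyd")
  atp_plus <- stats::na.omit(match(c("L_Emp", "Pyk", "PTACK", "aKGDH"), rxid))
  atp_minus <- stats::na.omit(match(c("Glk", "Pfk", "Pps", "Pck", "Acs"), rxid))
  co2_plus <- stats::na.omit(match(c("PGDH", "PDH", "ICDH", "aKGDH", "Mez", "Pck"), rxid))
  co2_minus <- stats::na.omit(match("Ppc", rxid))
  k_atp <- params[["k_ATP"]]

  bm <- network$biomass
  bm_prec <- bm$precursor
  bm_per_mu <- params[[bm$carbon_content]] * 1000 /
    (12.011 * network$species[[bm_prec]]$carbon)
  i_prec <- match(bm_prec, cyt_ids)

  i_ext <- match(ext_ids, state_ids); i_x <- match("X", state_ids)
  i_cyt <- match(cyt_ids, state_ids); i_pool <- match(pool_ids, state_ids)
  i_co2 <- match("CO2cum", state_ids)
  i_bmc <- match("BMCcum", state_ids)
  prec_carbon <- network$species[[bm_prec]]$carbon
  i_glc <- match("GLCx", state_ids)
  net_state_ids <- c(ext_ids, cyt_ids, pool_ids)
  i_net <- match(net_state_ids, state_ids)
  i_q <- match("Q", state_ids)
  n_rx <- length(rxid)

  make_rhs <- function(o2, tf_fnr) {
    reg <- split_regulation(network, params, tf_fnr)
    fnr_fac <- reg$fnr_fac; arca_edges <- reg$arca_edges
    arca_scale <- model$arca_scale
    function(t, y, parms) {
      st <- y[i_net]; names(st) <- net_state_ids
      cc <- full_concentrations(model, st, o2 = o2)
      tf_arca <- arca_scale * arca_activity(max(y[i_q], 0), params)
      f <- fnr_fac
      for (e in arca_edges)
        f[e$j] <- f[e$j] * if (e$act) 1 + e$s * tf_arca else 1 / (1 + e$s * tf_arca)
      v <- eval_fluxes_cc(model, cc, f)
      if (any(!is.finite(v)))
        stop("non-finite flux in reaction(s): ",
             paste(rxid[!is.finite(v)], collapse = ", "))
      op <- (4 * v[j_nuo] + 4 * v[j_cyo] + 2 * v[j_cyd]) / 3
      v_atp <- op + sum(v[atp_plus]) - sum(v[atp_minus])
      mu <- max(k_atp * v_atp, 0)
      x <- y[i_x]
      dy <- numeric(length(y))
      dy[i_ext] <- (S_ext %*% v) * ext_w * x
      dy[i_cyt] <- S_cyt %*% v - mu * y[i_cyt]
      # biomass precursor drain, saturable so it vanishes with the pool
      prec <- max(y[i_cyt[i_prec]], 0)
      v_bm <- mu * bm_per_mu * prec / (prec + 0.005)
      dy[i_cyt[i_prec]] <- dy[i_cyt[i_prec]] - v_bm
      dy[i_pool] <- S_pool %*% v
      dy[i_x] <- mu * x
      dy[i_co2] <- (sum(v[co2_plus]) - sum(v[co2_minus])) * x
      dy[i_bmc] <- v_bm * prec_carbon * x  # mmol biomass C per litre
      list(dy)
    }
  }

  rootfun <- function(t, y, parms) y[i_glc] - protocol$glc_threshold

  sched <- protocol$do
  seg_bounds <- c(sched$time, protocol$t_max)
  out_all <- NULL
  y <- y0; t0 <- 0; depleted <- FALSE; t_dep <- NA_real_
  if (y0[["GLCx"]] <= protocol$glc_threshold) {
    # already at (or below) the depletion threshold: a zero-length batch
    out_all <- as.data.frame(t(c(time = 0, y0)))
    out_all$DO_percent <- sched$do[1]
    depleted <- TRUE; t_dep <- 0
  } else for (k in seq_len(nrow(sched))) {
    t1 <- seg_bounds[k + 1L]
    if (t1 <= t0) next
    do_k <- sched$do[k]
    o2 <- do_percent_to_o2(do_k, params)
    tf_fnr <- model$fnr_scale * fnr_activity(o2, params)
    times <- unique(c(seq(t0, t1, by = dt_out), t1))
    sol <- deSolve::lsodar(y = y, times = times, func = make_rhs(o2, tf_fnr),
                           parms = NULL, rtol = rtol, atol = atol,
                           rootfunc = rootfun, maxsteps = 100000)
    attr_troot <- attributes(sol)$troot
    seg <- as.data.frame(sol)
    names(seg) <- c("time", state_ids)
    seg$DO_percent <- do_k
    out_all <- if (is.null(out_all)) seg else
      rbind(out_all, seg[seg$time > t0, , drop = FALSE])
    yend <- sol[nrow(sol), state_ids]
    if (!is.null(attr_troot) && length(attr_troot) > 0L) {
      depleted <- TRUE
      t_dep <- attr_troot[1]
      break
    }
    y <- yend; t0 <- t1
  }

  traj <- structure(list(
    time_series = out_all, t_dep = t_dep, depleted = depleted,
    protocol = protocol, params = params, network = network,
    solver = list(method = "lsodar", rtol = rtol, atol = atol,
                  dt_out = dt_out),
    digest = parameter_digest(params)
  ), class = "batch_trajectory")
  traj$time_series <- annotate_trajectory(traj, model)
  traj
}

# Recompute fluxes, TF activities and derived rates at every saved row.
annotate_trajectory <- function(traj, model) {
  ts <- traj$time_series
  params <- traj$params
  network <- traj$network
  rxid <- network$reaction_ids
  n <- nrow(ts)
  vmat <- matrix(0, n, length(rxid), dimnames = list(NULL, paste0("v_", rxid)))
  tfs <- matrix(0, n, 2, dimnames = list(NULL, c("TF_Fnr", "TF_ArcA")))
  der <- matrix(0, n, 7, dimnames = list(
    NULL, c("v_ATP", "OP", "mu", "v_CO2", "v_NADPH", "v_NADH", "qOUR")))
  comp <- model$compartment
  net_ids <- names(comp)[comp %in% c("extracellular", "cytoplasm", "pool")]
  for (i in seq_len(n)) {
    st <- as.numeric(ts[i, net_ids]); names(st) <- net_ids
    o2 <- do_percent_to_o2(ts$DO_percent[i], params)
    tf_fnr <- model$fnr_scale * fnr_activity(o2, params)
    tf_arca <- model$arca_scale * arca_activity(max(st[["Q"]], 0), params)
    f <- regulation_factors(network, params, tf_fnr, tf_arca)
    cc <- full_concentrations(model, st, o2 = o2)
    v <- eval_fluxes_cc(model, cc, f)
    vmat[i, ] <- v
    tfs[i, ] <- c(tf_fnr, tf_arca)
    a <- atp_rate(v)
    der[i, ] <- c(a$v_ATP, a$OP, growth_rate(a$v_ATP, params),
                  co2_rate(v), nadph_rate(v), nadh_rate(v)$v_NADH,
                  respiratory_o2_consumption(v))
  }
  ts$O2_cyt <- do_percent_to_o2(ts$DO_percent, params)
  ts$condition <- classify_condition(ts$DO_percent)
  ts$NADH_ratio <- ts$NADH / (params[["NAD_total"]] - ts$NADH)
  cbind(ts, as.data.frame(tfs), as.data.frame(der), as.data.frame(vmat))
}

#' Product concentrations at glucose depletion
#'
#' @param trajectory a depleted `batch_trajectory`.
#' @return named vector (g/l): acetate, lactate, formate, ethanol,
#'   succinate, plus `t_dep` (h) and biomass `X` (gDW/l) as attributes-free
#'   extra entries.
#' @export
products_at_depletion <- function(trajectory) {
  if (!isTRUE(trajectory$depleted))
    stop("trajectory did not reach glucose depletion")
  last <- trajectory$time_series[nrow(trajectory$time_series), ]
  c(acetate = last$ACEx, lactate = last$LACx, formate = last$FORx,
    ethanol = last$ETHx, succinate = last$SUCx,
    t_dep = trajectory$t_dep, X = last$X)
}

#' @export
print.batch_trajectory <- function(x, ...) {
  cat(sprintf("<batch_trajectory> strain %s, %s\n",
              x$protocol$strain$name,
              if (x$depleted) sprintf("glucose depleted at %.3f h", x$t_dep)
              else "glucose NOT depleted"))
  if (x$depleted) {
    p <- products_at_depletion(x)
    cat(sprintf("  products (g/l): %s\n",
                paste(sprintf("%s %.3f", names(p)[1:5], p[1:5]), collapse = ", ")))
  }
  invisible(x)
}

#' Integrate a network at a fixed environment
#'
#' Generic constant-environment integrator (no biomass, no growth dilution):
#' used for toy networks and steady-state checks.  Boundary species with a
#' `fixed` field take their concentration from the parameter set.
#'
#' @param network a `metabolic_network`.
#' @param params a `parameter_set`.
#' @param y0 named initial state (cytoplasm + pool members); defaults to the
#'   network's `init` fields.
#' @param times output time points.
#' @param do_percent fixed DO level for the TF activities (default 0).
#' @return data frame of the integrated states over `times`.
#' @export
simulate_network <- function(network, params, y0 = NULL, times,
                             do_percent = 0) {
  model <- compile_model(network, params)
  comp <- model$compartment
  state_ids <- names(comp)[comp %in% c("cytoplasm", "pool", "extracellular")]
  if (is.null(y0)) {
    y0 <- vapply(state_ids, function(id)
      as.numeric(network$species[[id]]$init %||% 0), 0)
    names(y0) <- state_ids
  }
  fixed <- list()
  for (s in network$species)
    if (identical(s$compartment, "boundary") && !is.null(s$fixed))
      fixed[[s$id]] <- params[[s$fixed]]
  o2 <- do_percent_to_o2(do_percent, params)
  tf_fnr <- model$fnr_scale * fnr_activity(o2, params)
  has_q <- "Q" %in% state_ids
  S_state <- model$S[state_ids, , drop = FALSE]
  rhs <- function(t, y, parms) {
    st <- y; names(st) <- state_ids
    cc <- full_concentrations(model, st, o2 = o2)
    for (id in names(fixed)) cc[[id]] <- fixed[[id]]
    tf_arca <- if (has_q && "K_ArcA" %in% names(params))
      model$arca_scale * arca_activity(max(st[["Q"]], 0), params) else 0
    f <- regulation_factors(network, params, tf_fnr, tf_arca)
    v <- eval_fluxes_cc(model, cc, f)
    list(as.numeric(S_state %*% v))
  }
  sol <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("time", state_ids)
  out
}
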