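# In-silico experiments: DO sweeps with product/flux summaries, peak
# localization, and the dual-phase (aerobic -> micro-aerobic) switching-time
# scan for lactate production.

#' Sweep dissolved-oxygen setpoints for a strain
#'
#' Runs one batch simulation per DO grid point and summarizes each depleted
#' run: product concentrations at glucose depletion, depletion time, mean
#' TF activities and NADH/NAD+ ratio over the final phase of the batch, the
#' specific oxygen uptake rate, and the key pyruvate-node and respiratory
#' fluxes.  Non-depleted runs are flagged in the `depleted` column, never
#' dropped.
#'
#' @param strain a `strain_spec` or shortcut name.
#' @param do_grid increasing vector of DO percentages; the default resolves
#'   the 0-7 percent regime where the metabolic shift is steepest.
#' @param protocol base protocol; its DO schedule is overridden per grid
#'   point.
#' @param network,params model definition.
#' @param ... passed to [simulate_batch()].
#' @return a data frame of class `do_sweep`, one row per DO level.
#' @export
do_sweep <- function(strain = "WT",
                     do_grid = c(0:20, 25, 30, 35, 40),
                     protocol = cultivation_protocol(),
                     network = ecoli_network(),
                     params = default_parameters(), ...) {
  stopifnot(!is.unsorted(do_grid, strictly = TRUE),
            all(do_grid >= 0 & do_grid <= 100))
  if (is.character(strain)) strain <- strain_spec(strain)
  rows <- lapply(do_grid, function(do) {
    pr <- protocol
    pr$do <- data.frame(time = 0, do = do)
    pr$strain <- strain
    traj <- simulate_batch(pr, network = network, params = params, ...)
    ts <- traj$time_series
    # summarize the regulatory/flux state over the mid-batch (between 25 and
    # 75 percent of glucose consumed), away from inoculation transients
    gl <- ts$GLCx
    mid <- gl <= 0.75 * gl[1] & gl >= 0.25 * gl[1]
    if (!any(mid)) mid <- rep(TRUE, nrow(ts))
    m <- function(col) mean(ts[[col]][mid])
    prod <- if (traj$depleted) products_at_depletion(traj) else
      c(acetate = NA_real_, lactate = NA_real_, formate = NA_real_,
        ethanol = NA_real_, succinate = NA_real_, t_dep = NA_real_,
        X = NA_real_)
    data.frame(
      DO_percent = do, condition = classify_condition(do),
      depleted = traj$depleted,
      acetate = prod[["acetate"]], lactate = prod[["lactate"]],
      formate = prod[["formate"]], ethanol = prod[["ethanol"]],
      succinate = prod[["succinate"]], t_dep = prod[["t_dep"]],
      X_final = prod[["X"]],
      TF_Fnr = m("TF_Fnr"), TF_ArcA = m("TF_ArcA"),
      NADH_ratio = m("NADH_ratio"), qOUR = m("qOUR"),
      v_Pfl = m("v_Pfl"), v_PDH = m("v_PDH"), v_LDH = m("v_LDH"),
      v_ADH = m("v_ADH"), v_Frd = m("v_Frd"), v_Cyo = m("v_Cyo"),
      v_Cyd = m("v_Cyd"), mu = m("mu")
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "strain") <- strain$name
  class(out) <- c("do_sweep", "data.frame")
  out
}

#' Locate the DO level maximizing a product concentration
#'
#' Grid argmax with quadratic refinement from the two neighboring points;
#' ties are broken toward the lower DO level.  A maximum at a grid endpoint
#' is reported with `interior = FALSE` (monotone profile, no interior peak).
#'
#' @param sweep a `do_sweep`.
#' @param product one of "acetate", "lactate", "formate", "ethanol",
#'   "succinate".
#' @return list with `do_peak` (refined), `do_grid_peak`, `value`,
#'   `interior` flag and `flat` flag.
#' @export
find_peak <- function(sweep, product = "lactate") {
  y <- sweep[[product]]
  x <- sweep$DO_percent
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 2L) stop("sweep too short for peak finding")
  if (diff(range(y)) < 1e-12 * max(abs(y), 1))
    return(list(do_peak = NA_real_, do_grid_peak = NA_real_,
                value = y[1], interior = FALSE, flat = TRUE))
  i <- which(y == max(y))[1L]  # ties -> lower DO
  interior <- i > 1L && i < length(y)
  do_ref <- x[i]
  if (interior) {
    # quadratic through the three bracketing points
    xs <- x[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
    d <- (ys[3] - ys[1]) / ((xs[3] - xs[1]))
    c2 <- ((ys[3] - ys[2]) / (xs[3] - xs[2]) -
             (ys[2] - ys[1]) / (xs[2] - xs[1])) / (xs[3] - xs[1])
    if (c2 < 0) {
      v <- (xs[1] + xs[3]) / 2 - d / (2 * c2) +
        (xs[2] - (xs[1] + xs[3]) / 2) * 0  # vertex of the fitted parabola
      # clamp refinement to one grid step around the argmax
      v <- min(max(v, x[i - 1]), x[i + 1])
      do_ref <- v
    }
  }
  list(do_peak = do_ref, do_grid_peak = x[i], value = y[i],
       interior = interior, flat = FALSE)
}

#' Scan dual-phase switching times for lactate production
#'
#' For each switching time `t_s`, the culture runs at the aerobic DO level
#' on `[0, t_s)` and at the micro-aerobic level thereafter, until glucose
#' depletion.  Yield is g lactate per g glucose consumed; productivity is
#' the final lactate concentration divided by the cultivation time (time to
#' depletion).  `t_s = 0` degenerates to the constant micro-aerobic batch.
#'
#' @param strain a `strain_spec` or shortcut name (the lactate design case
#'   is the `pfl` knockout).
#' @param do_aero,do_micro DO percentages of the two phases.
#' @param switch_grid vector of switching times (h).
#' @param protocol base protocol (glucose, inoculum, stop condition).
#' @param network,params model definition.
#' @param ... passed to [simulate_batch()].
#' @return a data frame of class `dual_phase_result`, one row per switching
#'   time, with `yield`, `productivity`, `lactate`, `t_dep`, `depleted`.
#' @export
dual_phase_scan <- function(strain = "pfl", do_aero = 40, do_micro = 1,
                            switch_grid = seq(0, 12, by = 0.5),
                            protocol = cultivation_protocol(),
                            network = ecoli_network(),
                            params = default_parameters(), ...) {
  if (is.character(strain)) strain <- strain_spec(strain)
  rows <- lapply(switch_grid, function(ts_h) {
    pr <- protocol
    pr$strain <- strain
    pr$do <- if (ts_h <= 0) data.frame(time = 0, do = do_micro)
             else data.frame(time = c(0, ts_h), do = c(do_aero, do_micro))
    traj <- simulate_batch(pr, network = network, params = params, ...)
    if (traj$depleted) {
      p <- products_at_depletion(traj)
      consumed <- pr$glc0 - traj$time_series$GLCx[nrow(traj$time_series)]
      data.frame(t_switch = ts_h, depleted = TRUE,
                 lactate = p[["lactate"]], t_dep = p[["t_dep"]],
                 glucose_consumed = consumed,
                 yield = p[["lactate"]] / consumed,
                 productivity = p[["lactate"]] / p[["t_dep"]])
    } else {
      data.frame(t_switch = ts_h, depleted = FALSE, lactate = NA_real_,
                 t_dep = NA_real_, glucose_consumed = NA_real_,
                 yield = NA_real_, productivity = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "strain") <- strain$name
  attr(out, "do_aero") <- do_aero
  attr(out, "do_micro") <- do_micro
  class(out) <- c("dual_phase_result", "data.frame")
  out
}

#' Optimal switching time of a dual-phase scan
#'
#' @param scan a `dual_phase_result`.
#' @param objective column to maximize ("productivity" or "yield").
#' @return list with `t_switch`, `value`, and the corresponding row.
#' @export
optimal_switch <- function(scan, objective = "productivity") {
  ok <- which(scan$depleted & !is.na(scan[[objective]]))
  if (length(ok) == 0L) stop("no depleted runs in the scan")
  i <- ok[which.max(scan[[objective]][ok])]
  list(t_switch = scan$t_switch[i], value = scan[[objective]][i],
       row = scan[i, ])
}
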