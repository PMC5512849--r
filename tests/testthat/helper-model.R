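# Shared model objects and memoised expensive simulations.  test_dir() runs
# all files in one session, so the cache is filled once and reused.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

the_network <- function() memo("network", ecoli_network())
the_params  <- function() memo("params", default_parameters())

# small, fast batch (low glucose, generous inoculum) for unit-level checks
quick_protocol <- function(do = 10, strain = "WT", glc0 = 2, x0 = 0.3) {
  cultivation_protocol(glc0 = glc0, x0 = x0, do = do, strain = strain)
}

quick_batch <- function(do = 10, strain = "WT", ...) {
  memo(sprintf("qb_%s_%s", strain, do),
       simulate_batch(quick_protocol(do = do, strain = strain, ...),
                      the_network(), the_params()))
}

# full paper-scale batches and sweeps (10 g/l glucose), shared between the
# qualitative and acceptance tests
full_batch <- function(do, strain = "WT") {
  memo(sprintf("fb_%s_%s", strain, do),
       simulate_batch(cultivation_protocol(do = do, strain = strain),
                      the_network(), the_params()))
}

full_sweep <- function(strain, grid = c(0:20, 25, 30, 35, 40)) {
  memo(sprintf("sweep_%s", strain), {
    rows <- lapply(grid, function(d) {
      tr <- full_batch(d, strain)
      p <- products_at_depletion(tr)
      ts <- tr$time_series
      gl <- ts$GLCx
      mid <- gl <= 0.75 * gl[1] & gl >= 0.25 * gl[1]
      data.frame(DO_percent = d, condition = classify_condition(d),
                 depleted = tr$depleted,
                 acetate = p[["acetate"]], lactate = p[["lactate"]],
                 formate = p[["formate"]], ethanol = p[["ethanol"]],
                 succinate = p[["succinate"]], t_dep = p[["t_dep"]],
                 X_final = p[["X"]],
                 TF_Fnr = mean(ts$TF_Fnr[mid]), TF_ArcA = mean(ts$TF_ArcA[mid]),
                 NADH_ratio = mean(ts$NADH_ratio[mid]),
                 qOUR = mean(ts$qOUR[mid]))
    })
    out <- do.call(rbind, rows)
    class(out) <- c("do_sweep", "data.frame")
    out
  })
}

dual_phase_cached <- function() {
  memo("dual_phase",
       dual_phase_scan(strain = "pfl", do_aero = 40, do_micro = 1,
                       switch_grid = seq(0, 12, by = 0.5),
                       network = the_network(), params = the_params()))
}

# independent dot-product oracle for the derived-rate equations: signed
# coefficient vector applied to an arbitrary named flux vector
dot_oracle <- function(fluxes, coef) {
  sum(vapply(names(coef), function(id)
    coef[[id]] * (if (id %in% names(fluxes)) fluxes[[id]] else 0), 0))
}

random_flux_vector <- function(rxids, seed) {
  set.seed(seed)
  v <- stats::runif(length(rxids), 0, 20)
  names(v) <- rxids
  v
}
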