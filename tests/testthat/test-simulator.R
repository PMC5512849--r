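test_that("conserved pools stay constant along trajectories", {
  p <- the_params()
  for (tr in list(quick_batch(10), quick_batch(0), full_batch(1, "pfl"))) {
    ts <- tr$time_series
    nad_tot <- p[["NAD_total"]]; q_tot <- p[["Q_total"]]
    # tracked members must stay inside [0, total] (partner non-negative)
    expect_true(all(ts$NADH >= -1e-8 & ts$NADH <= nad_tot + 1e-8))
    expect_true(all(ts$Q >= -1e-8 & ts$Q <= q_tot + 1e-8))
    # the pool sums are constants of the motion by construction; verify the
    # assembled derivative is exactly zero at sampled states
    model <- compile_model(tr$network, tr$params)
    S <- model$S
    for (i in c(1L, nrow(ts) %/% 2L, nrow(ts))) {
      st <- as.numeric(ts[i, model$state_ids]); names(st) <- model$state_ids
      env <- redox_environment(ts$DO_percent[i], q = max(st[["Q"]], 0),
                               params = tr$params,
                               fnr_scale = model$fnr_scale,
                               arca_scale = model$arca_scale)
      v <- evaluate_fluxes(st, env, tr$network, tr$params)
      expect_lt(abs(sum(S["NADH", ] * v) + sum(S["NADp", ] * v)), 1e-12)
      expect_lt(abs(sum(S["Q", ] * v) + sum(S["QH2", ] * v)), 1e-12)
    }
  }
})

test_that("all accepted concentrations are non-negative", {
  # dense-output interpolation between accepted steps can undershoot zero
  # slightly on near-zero states; anything beyond 1e-5 would indicate a
  # genuine integration failure
  for (tr in list(quick_batch(10), quick_batch(0))) {
    ts <- tr$time_series
    model <- compile_model(tr$network, tr$params)
    cols <- c(model$state_ids, "X")
    expect_true(all(as.matrix(ts[, cols]) > -1e-5))
  }
})

test_that("glucose depletion event is located at the threshold", {
  tr <- quick_batch(10)
  expect_true(tr$depleted)
  last <- tr$time_series[nrow(tr$time_series), ]
  expect_lt(abs(last$GLCx - tr$protocol$glc_threshold), 1e-6)
  expect_equal(last$time, tr$t_dep, tolerance = 1e-8)
})

test_that("degenerate protocols behave sensibly", {
  net <- the_network(); p <- the_params()
  # no glucose: depletion at t = 0 (first root), no products formed
  tr <- simulate_batch(cultivation_protocol(glc0 = 0.009, x0 = 0.1),
                       net, p)
  expect_true(tr$depleted)
  expect_lt(tr$t_dep, 1e-6)
  expect_lt(max(tr$time_series$LACx), 1e-9)
  # biomass can never decrease (no death term)
  tr2 <- quick_batch(5)
  expect_true(all(diff(tr2$time_series$X) >= -1e-12))
})

test_that("more inoculum strictly shortens the batch", {
  net <- the_network(); p <- the_params()
  t1 <- simulate_batch(cultivation_protocol(glc0 = 2, x0 = 0.2, do = 10),
                       net, p)$t_dep
  t2 <- simulate_batch(cultivation_protocol(glc0 = 2, x0 = 0.4, do = 10),
                       net, p)$t_dep
  expect_lt(t2, t1)
})

test_that("halving solver tolerances leaves final products essentially unchanged", {
  net <- the_network(); p <- the_params()
  pr <- quick_protocol(do = 5)
  a <- products_at_depletion(simulate_batch(pr, net, p,
                                            rtol = 1e-8, atol = 1e-10))
  b <- products_at_depletion(simulate_batch(pr, net, p,
                                            rtol = 5e-9, atol = 5e-11))
  rel <- abs(a - b) / pmax(abs(a), 1e-6)
  expect_lt(max(rel[1:5]), 1e-4)
})

test_that("identical protocols give bit-identical output (determinism)", {
  net <- the_network(); p <- the_params()
  pr <- quick_protocol(do = 7)
  a <- simulate_batch(pr, net, p)
  b <- simulate_batch(pr, net, p)
  expect_identical(a$time_series, b$time_series)
  expect_identical(a$t_dep, b$t_dep)
})

test_that("DO switching restarts integration and switches the regulatory state", {
  net <- the_network(); p <- the_params()
  pr <- cultivation_protocol(glc0 = 4, x0 = 0.2,
                             do = data.frame(time = c(0, 1.5), do = c(40, 1)))
  tr <- simulate_batch(pr, net, p)
  ts <- tr$time_series
  expect_setequal(unique(ts$DO_percent), c(40, 1))
  before <- ts$TF_Fnr[ts$time < 1.5]
  after <- ts$TF_Fnr[ts$time > 2.5]
  expect_lt(max(before), 0.01)   # aerobic phase: Fnr off
  expect_gt(min(after), 0.9)     # micro-aerobic phase: Fnr on
})

test_that("products_at_depletion refuses non-depleted runs", {
  net <- the_network(); p <- the_params()
  pr <- cultivation_protocol(glc0 = 10, x0 = 0.001, do = 0, t_max = 0.5)
  tr <- simulate_batch(pr, net, p)
  expect_false(tr$depleted)
  expect_error(products_at_depletion(tr), "not reach")
})

test_that("quinone pool balances reduction against oxidation after transients", {
  # along a quasi-steady stretch of the batch, d[Q]/dt is small relative to
  # the pool turnover: reduction (Nuo+Ndh) ~ oxidation (Cyo+Cyd+Frd), and the
  # spec equality Nuo+Ndh = Cyo+Cyd holds where Frd is silent (aerobic)
  tr <- full_batch(40, "WT")
  ts <- tr$time_series
  mid <- ts$time > 1 & ts$GLCx > 1
  red <- ts$v_Nuo[mid] + ts$v_Ndh[mid]
  ox <- ts$v_Cyo[mid] + ts$v_Cyd[mid] + ts$v_Frd[mid]
  expect_lt(max(abs(red - ox) / pmax(red, 1e-6)), 1e-2)
  expect_lt(max(ts$v_Frd[mid] / red), 5e-3)  # aerobic: Frd silent
  # anaerobic endpoint: no terminal electron acceptor, so at the relaxed pool
  # the NADH dehydrogenases only run against Frd
  tr0 <- full_batch(0, "WT")
  ts0 <- tr0$time_series
  mid0 <- ts0$time > 2 & ts0$GLCx > 1
  expect_true(all(ts0$v_Cyo[mid0] == 0 & ts0$v_Cyd[mid0] == 0))
  red0 <- ts0$v_Nuo[mid0] + ts0$v_Ndh[mid0]
  expect_lt(max(abs(red0 - ts0$v_Frd[mid0]) / pmax(red0, 1e-6)), 1e-2)
})
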