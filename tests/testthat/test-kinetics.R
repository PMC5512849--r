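test_that("fluxes vanish without substrates and respiration needs oxygen", {
  net <- the_network(); p <- the_params()
  ids <- names(net$species)[vapply(net$species, function(s)
    s$compartment %in% c("extracellular", "cytoplasm", "pool"), TRUE)]
  zero <- stats::setNames(rep(0, length(ids)), ids)
  # pool members are complements: zero substrates means NADH = 0 (all NAD+)
  # and a fully oxidized quinone pool (QH2 = 0)
  zero["Q"] <- p[["Q_total"]]
  v0 <- evaluate_fluxes(zero, env = 40, network = net, params = p)
  expect_true(all(abs(v0) < 1e-12))
  # generic state, anaerobic: terminal oxidases are silent
  st <- zero
  st[c("GLCx", "G6P", "F6P", "FBP", "GAP", "PEP", "PYR", "AcCoA", "ACAL",
       "CIT", "AKG", "SUCi", "FUM", "MAL", "OAA")] <- 0.5
  st["NADH"] <- 1; st["Q"] <- 0.4
  v <- evaluate_fluxes(st, env = 0, network = net, params = p)
  expect_identical(unname(v[["Cyo"]]), 0)
  expect_identical(unname(v[["Cyd"]]), 0)
  expect_gt(v[["Nuo"]], 0)
})

test_that("negative concentrations beyond tolerance are rejected with the species named", {
  net <- the_network(); p <- the_params()
  ids <- names(net$species)[vapply(net$species, function(s)
    s$compartment %in% c("extracellular", "cytoplasm", "pool"), TRUE)]
  st <- stats::setNames(rep(0.1, length(ids)), ids)
  st["PYR"] <- -1e-4
  expect_error(evaluate_fluxes(st, env = 10, network = net, params = p), "PYR")
  # tiny numerical undershoot is treated as zero
  st["PYR"] <- -1e-12
  expect_silent(evaluate_fluxes(st, env = 10, network = net, params = p))
})

test_that("ADH rate rises with the NADH/NAD+ ratio, all else fixed", {
  net <- the_network(); p <- the_params()
  ids <- names(net$species)[vapply(net$species, function(s)
    s$compartment %in% c("extracellular", "cytoplasm", "pool"), TRUE)]
  st <- stats::setNames(rep(0.3, length(ids)), ids)
  st["Q"] <- 0.01
  ratios <- c(0.2, 0.5, 1, 2, 5)
  nadh <- ratios / (1 + ratios) * p[["NAD_total"]]
  v_adh <- vapply(nadh, function(x) {
    st["NADH"] <- x
    evaluate_fluxes(st, env = 0, network = net, params = p)[["ADH"]]
  }, 0)
  expect_true(all(diff(v_adh) > 0))
})

test_that("oxygen affinity ordering: Cyd reaches half-maximum at lower DO than Cyo", {
  net <- the_network(); p <- the_params()
  expect_lt(p[["K_Cyd_O2"]], p[["K_Cyo_O2"]])
  ids <- names(net$species)[vapply(net$species, function(s)
    s$compartment %in% c("extracellular", "cytoplasm", "pool"), TRUE)]
  st <- stats::setNames(rep(0.3, length(ids)), ids)
  st["Q"] <- 0.5  # equal QH2 for both oxidases
  do_grid <- seq(0.1, 100, by = 0.1)
  vs <- vapply(do_grid, function(d) {
    v <- evaluate_fluxes(st, env = redox_environment(d, q = st[["Q"]], params = p),
                         network = net, params = p)
    c(v[["Cyo"]], v[["Cyd"]])
  }, c(0, 0))
  half_do <- function(y) do_grid[which.min(abs(y - (max(y) / 2)))]
  expect_lt(half_do(vs[2, ]), half_do(vs[1, ]))
})

test_that("qOUR is half the summed terminal-oxidase flux", {
  expect_identical(respiratory_o2_consumption(c(Cyo = 0, Cyd = 0, Nuo = 3)), 0)
  expect_identical(respiratory_o2_consumption(c(Cyo = 4, Cyd = 0)), 2)
  expect_identical(respiratory_o2_consumption(c(Cyo = 3, Cyd = 2)), 2.5)
})

test_that("fluxes vary continuously when effector terms are removed", {
  # finite-difference continuity scan: perturbing any concentration slightly
  # never jumps the flux vector (no hidden discontinuities in the rate laws)
  net <- the_network(); p <- the_params()
  ids <- names(net$species)[vapply(net$species, function(s)
    s$compartment %in% c("extracellular", "cytoplasm", "pool"), TRUE)]
  set.seed(7)
  st <- stats::setNames(stats::runif(length(ids), 0.05, 1), ids)
  st["Q"] <- min(st[["Q"]], 0.9)
  st["NADH"] <- min(st[["NADH"]], 1.8)
  v0 <- evaluate_fluxes(st, env = 5, network = net, params = p)
  h <- 1e-7
  for (id in sample(ids, 8)) {
    st2 <- st; st2[id] <- st2[id] + h
    v1 <- evaluate_fluxes(st2, env = 5, network = net, params = p)
    expect_lt(max(abs(v1 - v0)), 1e-3, label = sprintf("continuity in %s", id))
  }
})

test_that("electron bookkeeping of the quinone pool is structural", {
  # the Q row of the stoichiometric matrix encodes: reduction by Nuo/Ndh,
  # oxidation by Cyo/Cyd/Frd, nothing else
  net <- the_network()
  S <- stoichiometry_matrix(net)
  qrow <- S["Q", ]
  expect_identical(qrow[["Nuo"]], -1); expect_identical(qrow[["Ndh"]], -1)
  expect_identical(qrow[["Cyo"]], 1); expect_identical(qrow[["Cyd"]], 1)
  expect_identical(qrow[["Frd"]], 1)
  expect_true(all(qrow[setdiff(names(qrow), c("Nuo", "Ndh", "Cyo", "Cyd", "Frd"))] == 0))
  # hence at a quasi-steady pool, reduction equals oxidation:
  # v_Nuo + v_Ndh = v_Cyo + v_Cyd + v_Frd (and = v_Cyo + v_Cyd when Frd is silent)
  v <- random_flux_vector(net$reaction_ids, seed = 11)
  expect_equal(sum(qrow * v), (v[["Cyo"]] + v[["Cyd"]] + v[["Frd"]]) -
                 (v[["Nuo"]] + v[["Ndh"]]), tolerance = 1e-12)
})
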