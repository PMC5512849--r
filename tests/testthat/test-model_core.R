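test_that("shipped network passes validation and carries the canonical enzymes", {
  net <- the_network()
  rep <- validate_network(net)
  expect_true(rep$ok)
  expect_length(rep$violations, 0)
  needed <- c("PTS", "Glk", "Pfk", "Fba", "L_Emp", "Pyk", "Pps", "PDH",
              "Pfl", "LDH", "ALDH", "ADH", "PTACK", "Acs", "CS", "ICDH",
              "aKGDH", "SDH", "Frd", "Fum", "MDH", "Mez", "Pck", "Ppc",
              "Icl", "MS", "G6PDH", "PGDH", "Rpe", "Rpi", "TktA", "TktB",
              "Tal", "Fbp", "Nuo", "Ndh", "Cyo", "Cyd", "npts")
  expect_true(all(needed %in% net$reaction_ids))
})

test_that("validation reports structural damage exhaustively", {
  net <- the_network()
  # break a pool row sum: NADH without the NAD+ counterpart
  net$reactions$L_Emp$stoichiometry$NADp <- NULL
  # and drop a canonical oxidase
  net$reactions$Cyd <- NULL
  net$reaction_ids <- setdiff(net$reaction_ids, "Cyd")
  rep <- validate_network(net)
  expect_false(rep$ok)
  expect_true(any(grepl("pool NAD", rep$violations)))
  expect_true(any(grepl("missing canonical reaction Cyd", rep$violations)))
})

test_that("every reaction is carbon balanced on declared carbon counts", {
  net <- the_network()
  carbon <- vapply(net$species, function(s) as.numeric(s$carbon %||% 0), 0)
  names(carbon) <- net$species_ids
  for (rx in net$reactions) {
    st <- rx$stoichiometry
    cb <- sum(vapply(names(st), function(sp)
      st[[sp]] * (if (sp %in% names(carbon)) carbon[[sp]] else 0), 0))
    expect_equal(cb, 0, tolerance = 1e-12,
                 label = sprintf("carbon balance of %s", rx$id))
  }
})

test_that("regulation table contains every documented Fnr/ArcA edge", {
  net <- the_network()
  edges <- vapply(net$regulation, function(e)
    paste(e$tf, e$reaction, e$sign), "")
  required <- c(
    "ArcA Cyo repression",   # phosphorylated ArcA represses cyoABCD
    "ArcA Cyd activation",   # and activates cydAB
    "ArcA Pfl activation",
    "ArcA PDH repression",   # aceE/F
    "ArcA CS repression", "ArcA ICDH repression",
    "ArcA aKGDH repression", "ArcA SDH repression",  # TCA-cycle genes
    "Fnr Frd activation",
    "Fnr Cyd repression",
    "Fnr Ndh repression",    # NADH dehydrogenase
    "Fnr Pfl activation",
    "Fnr CS repression", "Fnr ICDH repression",
    "Fnr aKGDH repression", "Fnr SDH repression")
  for (e in required) expect_true(e %in% edges, label = e)
})

test_that("parameter loading validates exhaustively, not one error at a time", {
  net <- the_network()
  tab <- attr(the_params(), "meta")
  bad <- tab
  bad$value[bad$symbol == "K_Fnr"] <- 0
  bad <- bad[bad$symbol != "k_ATP", ]
  err <- tryCatch(load_parameters(bad, network = net), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "K_Fnr")
  expect_match(conditionMessage(err), "k_ATP")
})

test_that("parameter set round-trips through CSV bit-for-bit", {
  p <- the_params()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_parameters(p, tmp)
  p2 <- load_parameters(tmp, network = the_network())
  expect_identical(unname(p[sort(names(p))]), unname(p2[sort(names(p2))]))
  expect_identical(parameter_digest(p), parameter_digest(p2))
})

test_that("yaml and csv parameter sources are both accepted", {
  p <- the_params()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(as.list(stats::setNames(as.numeric(p), names(p))), tmp)
  p2 <- load_parameters(tmp, network = the_network())
  expect_equal(unname(p2[names(p)]), unname(as.numeric(p)), tolerance = 1e-12)
})

test_that("knockouts follow their declared semantics", {
  net <- the_network(); par <- the_params()
  # WT is the identity
  wt <- apply_knockout(net, par, "WT")
  expect_identical(as.numeric(wt$params), as.numeric(par))
  expect_equal(attr(wt$params, "fnr_scale") %||% 1, 1)
  # fnr: Fnr activity identically zero
  kf <- apply_knockout(net, par, "fnr")
  expect_identical(attr(kf$params, "fnr_scale"), 0)
  # pfl: maximal rate of Pfl zeroed
  kp <- apply_knockout(net, par, "pfl")
  expect_identical(kp$params[["vmax_Pfl"]], 0)
  # unknown gene errors
  expect_error(apply_knockout(net, par, strain_spec("x", "ydjN")), "unknown")
})

test_that("apply_knockout is idempotent and commutative", {
  net <- the_network(); par <- the_params()
  once <- apply_knockout(net, par, "fnr")$params
  twice <- apply_knockout(net, once, "fnr")$params
  expect_identical(as.numeric(once), as.numeric(twice))
  expect_identical(attr(once, "fnr_scale"), attr(twice, "fnr_scale"))
  ab <- apply_knockout(net, apply_knockout(net, par, "fnr")$params, "arcA")$params
  ba <- apply_knockout(net, apply_knockout(net, par, "arcA")$params, "fnr")$params
  expect_identical(as.numeric(ab), as.numeric(ba))
  expect_identical(attr(ab, "fnr_scale"), attr(ba, "fnr_scale"))
  expect_identical(attr(ab, "arca_scale"), attr(ba, "arca_scale"))
})
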