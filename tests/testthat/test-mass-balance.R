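test_that("single-link toy balances by hand arithmetic", {
  m <- toy_chain(herb_b = 0.1, herb_qb = 10, prod_b = 1, prod_pb = 10)
  bal <- balance_model(m)
  # plant: eaten 0.1*10*1 = 1 of production 10 -> EE 0.1; nothing eats
  # or catches the herbivore -> EE 0
  expect_equal(bal$stats$ee[2], 0.1, tolerance = 1e-12)
  expect_equal(bal$stats$ee[1], 0, tolerance = 1e-12)
})

test_that("the balance identity holds for every living group", {
  for (model in list(kaptai_model(),
                     generate_web(synthetic_web_spec(seed = 11)))) {
    bal <- balance_model(model)
    s <- bal$stats
    g <- bal$model$groups
    liv <- s$type != "detritus"
    resid <- s$production * s$ee - s$predation -
      (g$landings + g$ba + g$migration)
    expect_true(all(abs(resid[liv]) < 1e-9 * pmax(s$production[liv], 1)))
  }
})

test_that("solver agrees with a brute-force nonlinear root-finder", {
  skip_if_not_installed("pracma")
  for (sd in c(2, 5, 8, 13)) {
    w <- generate_web(synthetic_web_spec(n_consumers = 5, tl_layers = 2,
                                         seed = sd))
    # hide one biomass so both a B and many EE unknowns are in play
    tr <- attr(w, "truth")
    cand <- which(w$groups$type == "consumer")
    wm <- mask_parameter(w, cand[1], "biomass")
    bal <- balance_model(wm)
    or <- oracle_balance(wm)
    liv <- wm$groups$type != "detritus"
    expect_equal(bal$model$groups$biomass, or$biomass, tolerance = 1e-8)
    expect_equal(bal$stats$ee[liv], or$ee[liv], tolerance = 1e-8)
  }
})

test_that("solving an already-complete model changes nothing", {
  bal <- balance_model(kaptai_model())
  complete <- bal$model                 # all B and EE now filled
  bal2 <- balance_model(complete)
  expect_equal(bal2$model$groups$biomass, bal$model$groups$biomass,
               tolerance = 1e-14)
  expect_equal(bal2$stats$ee, bal$stats$ee, tolerance = 1e-14)
})

test_that("structurally unsolvable systems are reported, not mangled", {
  # two unknown-B groups in a mutual-predation cycle whose production
  # terms exactly offset their consumption terms: a singular system
  g <- data.frame(name = c("A", "B", "Plant", "Det"),
                  type = c("consumer", "consumer", "producer", "detritus"),
                  biomass = c(NA, NA, 10, 1), pb = c(10, 10, 100, NA),
                  qb = c(10, 10, NA, NA), ee = c(1, 1, NA, NA),
                  landings = 0, stringsAsFactors = FALSE)
  d <- matrix(0, 4, 4)
  d[2, 1] <- 1; d[1, 2] <- 1   # A eats B, B eats A, nothing else
  m <- food_web_model(g, d)
  expect_error(balance_model(m), "unsolvable|singular")
})

test_that("EE outside [0,1] flags the model instead of aborting", {
  m <- toy_chain(herb_b = 2, herb_qb = 10, prod_b = 1, prod_pb = 10)
  bal <- expect_silent(balance_model(m))
  expect_false(bal$balanced)
  expect_identical(bal$unbalanced_groups, "Plant")   # EE = 20/10 = 2
})

test_that("derived statistics follow the published accounting identities", {
  bal <- balance_model(kaptai_model())
  s <- bal$stats
  zoo <- which(s$name == "Zooplankton")
  # FD = GS*Q + (1-EE)*P, with Q = 1799 and P = 449.75
  expect_equal(s$flow_to_detritus[zoo],
               0.2 * 1799 + (1 - s$ee[zoo]) * 449.75, tolerance = 1e-9)
  minnow <- which(s$name == "Minnow")
  expect_equal(s$ra[minnow], 1 - 3.26 / (76.2 * 0.8), tolerance = 1e-12)
  # landed consumer: EE = catch / production, FD closes the budget
  m <- toy_chain(landings = c(0.08, 0))
  b2 <- balance_model(m)
  expect_equal(b2$stats$ee[1], 0.08 / (0.1 * 1), tolerance = 1e-12)
  expect_equal(b2$stats$flow_to_detritus[1], 0.2 * 1 + (1 - 0.8) * 0.1,
               tolerance = 1e-12)
})

test_that("detritus efficiency is consumed share of inflow", {
  bal <- balance_model(kaptai_model())
  expect_equal(detritus_ee(bal),
               bal$stats$predation[15] / sum(bal$stats$flow_to_detritus,
                                             na.rm = TRUE),
               tolerance = 1e-12)
  # no detritivores -> EE 0
  m <- toy_chain()
  expect_equal(detritus_ee(balance_model(m)), 0)
})

test_that("sum of detritus flows matches the published total", {
  bal <- balance_model(kaptai_model())
  expect_close(bal$detritus_inflow, 1550.573, 0.5)
})
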