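test_that("trophic levels solve the diet fixed point exactly", {
  # pure herbivore sits exactly one level above the producer
  m <- toy_chain()
  tl <- trophic_levels(m$diet, m$groups$type)
  expect_equal(tl, c(2, 1, 1))
  # self-loop: zooplankton-style cannibal at 0.05 gives 1.95/0.95
  bal <- balance_model(kaptai_model())
  s <- bal$stats
  expect_equal(s$tl[s$name == "Zooplankton"], 1.95 / 0.95,
               tolerance = 1e-12)
  expect_close(s$tl[s$name == "Catfish"], 3.364, 0.005)
  expect_close(s$tl[s$name == "Carp"], 2.143, 0.005)
})

test_that("adding higher-TL prey never lowers a consumer's level", {
  set.seed(401)
  for (rep in 1:20) {
    w <- generate_web(synthetic_web_spec(n_consumers = 6, tl_layers = 3,
                                         seed = 500 + rep))
    tl <- trophic_levels(w$diet, w$groups$type)
    cons <- which(w$groups$type == "consumer")
    c_i <- sample(cons, 1)
    higher <- which(tl >= tl[c_i] - 1 + 1e-9 &
                      seq_along(tl) != c_i &
                      w$groups$type != "detritus")
    if (length(higher) == 0) next
    p <- higher[sample.int(length(higher), 1)]
    d2 <- w$diet
    mix <- 0.3
    d2[, c_i] <- d2[, c_i] * (1 - mix)
    d2[p, c_i] <- d2[p, c_i] + mix
    tl2 <- trophic_levels(d2, w$groups$type)
    expect_gte(tl2[c_i] + 1e-9, tl[c_i])
  }
})

test_that("omnivory is the diet-weighted variance of prey levels", {
  bal <- balance_model(kaptai_model())
  s <- bal$stats
  expect_close(s$oi[s$name == "Sheatfish"], 0.508, 0.005)
  expect_close(s$oi[s$name == "Glassfish"], 0.108, 0.005)
  # single-level diet has zero omnivory
  m <- toy_chain()
  tl <- trophic_levels(m$diet, m$groups$type)
  oi <- omnivory_index(m$diet, tl, m$groups$type)
  expect_equal(oi[1], 0)
})

test_that("level fractions are stochastic and consistent with TL", {
  w <- generate_web(synthetic_web_spec(seed = 21, cannibalism_prob = 0))
  fr <- tl_fractions(w$diet, w$groups$type)
  expect_true(all(abs(rowSums(fr$fractions) - 1) < 1e-9))
  # mean integer level recovers the fractional trophic level
  tl <- trophic_levels(w$diet, w$groups$type)
  tl_from_f <- as.vector(fr$fractions %*% seq_len(ncol(fr$fractions)))
  expect_equal(tl_from_f, tl, tolerance = 1e-8)
  # origin split partitions the fractions
  expect_equal(fr$origin$producer + fr$origin$detritus, fr$fractions,
               tolerance = 1e-12)
})

test_that("spine reproduces the published level-one outflows", {
  bal <- balance_model(kaptai_model())
  sp <- lindeman_spine(bal)
  expect_close(sp$levels$flow_to_next[1], 1894.9, 0.01 * 1894.9)
  expect_close(bal$stats$predation[15], 353.9, 0.01 * 353.9)
  # flows shrink going up the spine
  expect_true(all(diff(sp$levels$throughput) <= 1e-9))
})

test_that("each spine level closes its mass budget", {
  for (model in list(kaptai_model(),
                     generate_web(synthetic_web_spec(seed = 33)))) {
    bal <- balance_model(model)
    sp <- lindeman_spine(bal)
    lv <- sp$levels
    resid <- lv$throughput - (lv$flow_to_next + lv$export_catch +
                                lv$respiration + lv$flow_to_detritus)
    # the published lake diet is print-rounded, so closure there is at the
    # rounding scale; machine-built webs close to numerical precision
    tol <- if (identical(model$area_km2, 583)) 3e-3 else 1e-6
    expect_true(all(abs(resid) <= tol * pmax(lv$throughput, 1)))
  }
})

test_that("transfer efficiencies match the published table", {
  bal <- balance_model(kaptai_model())
  sp <- lindeman_spine(bal)
  te <- transfer_efficiency_table(sp)
  expect_close(te["all", "II"], 4.652, 0.1)
  expect_close(te["all", "mean"], 8.629, 0.3)
  expect_close(te["producer", "mean"], 8.446, 0.3)
  expect_close(te["detritus", "mean"], 9.352, 0.3)
  # efficiency rises monotonically up the spine, as published
  row <- te["all", 1:6]
  expect_true(all(diff(row) > 0))
  # about a third of all throughflow is of detritus origin
  expect_close(sp$detritus_fraction, 0.33, 0.02)
})

test_that("a lossless chain transfers at one hundred percent", {
  # herbivore assimilates everything (GS = 0), respires nothing
  # (P/B = Q/B) and is fully harvested: TE at level II is 100%
  m <- toy_chain(herb_b = 0.1, herb_qb = 10, herb_pb = 10,
                 landings = c(1, 0), unassim = 0)
  bal <- balance_model(m)
  sp <- lindeman_spine(bal)
  expect_equal(sp$levels$te_percent[2], 100, tolerance = 1e-9)
})
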