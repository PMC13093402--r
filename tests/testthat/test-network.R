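test_that("flow network entries are the balance-equation terms", {
  bal <- balance_model(kaptai_model())
  net <- build_flow_network(bal)
  # phytoplankton -> zooplankton flow: B * Q/B * DC = 12.85 * 140 * 0.8
  expect_equal(net$flows["Phytoplankton", "Zooplankton"], 1439.2,
               tolerance = 1e-9)
  expect_true(all(net$flows >= 0))
  # exports: catch plus unconsumed detritus surplus
  expect_close(sum(net$exports), 1207.552, 0.1)
  # throughflow sums to the standard TST decomposition (exact on webs
  # with machine-stochastic diets; print rounding limits the lake model)
  summ <- system_summary(net, bal)
  expect_equal(sum(net$throughflow), summ$tst, tolerance = 1e-5)
  w <- generate_web(synthetic_web_spec(seed = 8))
  bal2 <- balance_model(w)
  net2 <- build_flow_network(bal2)
  expect_equal(sum(net2$throughflow), system_summary(net2, bal2)$tst,
               tolerance = 1e-12)
})

test_that("system summary reproduces the published ecosystem table", {
  bal <- balance_model(kaptai_model())
  summ <- system_summary(build_flow_network(bal), bal)
  expect_close(summ$tst, 5997.488, 0.001 * 5997.488)
  expect_close(summ$total_consumption, 2071.815, 0.001 * 2071.815)
  expect_equal(summ$tnpp, 11.7 * 203, tolerance = 1e-9)
  expect_close(summ$tpp_tr, 2.034, 0.01)
  expect_close(summ$tpp_tb, 71.764, 0.5)
  expect_close(summ$mtlc, 2.586, 0.01)
  expect_close(summ$fmpl, 2.525, 0.01)
  expect_close(summ$shannon, 1.405, 0.005)
  expect_close(summ$gross_efficiency, 0.0045, 0.0002)
  expect_close(summ$ci, 0.426, 0.01)
  expect_close(summ$total_production, 2865.004, 0.5)
})

test_that("TST components add up exactly and NSP equals exports", {
  for (model in list(kaptai_model(),
                     generate_web(synthetic_web_spec(seed = 44)))) {
    bal <- balance_model(model)
    summ <- system_summary(build_flow_network(bal), bal)
    expect_equal(summ$total_consumption + summ$total_exports +
                   summ$total_respiration + summ$total_flows_to_detritus,
                 summ$tst, tolerance = 1e-9 * summ$tst)
    # on a closed (no-import) web net system production leaves as export
    expect_equal(summ$nsp, summ$total_exports,
                 tolerance = 1e-6 * summ$total_exports)
  }
})

test_that("Shannon diversity hits its analytic extremes", {
  g <- data.frame(name = c("A", "B", "C", "Plant", "Det"),
                  type = c(rep("consumer", 3), "producer", "detritus"),
                  biomass = c(2, 2, 2, 2, 1), pb = c(1, 1, 1, 50, NA),
                  qb = c(10, 10, 10, NA, NA), ee = NA_real_, landings = 0,
                  stringsAsFactors = FALSE)
  d <- matrix(0, 5, 5); d[4, 1:3] <- 1
  summ <- system_summary(build_flow_network(balance_model(
    food_web_model(g, d))), balance_model(food_web_model(g, d)))
  expect_equal(summ$shannon, log(4), tolerance = 1e-12)  # 4 equal groups
})

test_that("cycling index matches a truncated walk-sum oracle", {
  # small webs with genuine cycles: detritus feedback + cannibalism
  for (sd in c(3, 9, 27)) {
    w <- generate_web(synthetic_web_spec(n_consumers = 3, tl_layers = 2,
                                         cannibalism_prob = 0.6,
                                         seed = sd))
    bal <- balance_model(w)
    net <- build_flow_network(bal)
    fci <- finn_cycling(net)$fci_percent
    expect_equal(fci, oracle_fci(net), tolerance = 1e-8)
  }
  bal <- balance_model(kaptai_model())
  net <- build_flow_network(bal)
  expect_equal(finn_cycling(net)$fci_percent, oracle_fci(net),
               tolerance = 1e-8)
})

test_that("cycling behaves at both structural extremes", {
  # strictly acyclic web: no detritus pool, no cannibalism
  w <- generate_web(synthetic_web_spec(has_detritus = FALSE,
                                       cannibalism_prob = 0, seed = 3))
  net <- build_flow_network(balance_model(w))
  expect_equal(finn_cycling(net)$fci_percent, 0, tolerance = 1e-10)
  # two compartments exchanging almost all flow: FCI approaches 100%
  loop <- list(flows = matrix(c(0, 100, 100, 0), 2),
               imports = c(0.001, 0), exports = c(0.001, 0),
               respiration = c(0, 0), throughflow = c(100.001, 100),
               types = c("consumer", "consumer"), names = c("a", "b"))
  class(loop) <- "flow_network"
  expect_gt(finn_cycling(loop)$fci_percent, 99.9)
})

test_that("cycling and information indices are scale invariant", {
  bal <- balance_model(kaptai_model())
  net <- build_flow_network(bal)
  net2 <- net
  for (f in c("flows", "imports", "exports", "respiration", "throughflow"))
    net2[[f]] <- net[[f]] * 1000
  expect_equal(finn_cycling(net2)$fci_percent,
               finn_cycling(net)$fci_percent, tolerance = 1e-9)
  a1 <- ascendancy(net); a2 <- ascendancy(net2)
  expect_equal(a1$ascendancy_percent, a2$ascendancy_percent,
               tolerance = 1e-9)
  expect_equal(a1$ascendancy_percent + a1$overhead_percent, 100,
               tolerance = 1e-9)
})

test_that("ascendancy reproduces the published share of capacity", {
  bal <- balance_model(kaptai_model())
  a <- ascendancy(build_flow_network(bal))
  expect_close(a$ascendancy_percent, 32.09, 1.5)
  expect_close(a$overhead_percent, 67.91, 1.5)
})

test_that("a single deterministic flow is pure ascendancy", {
  one <- list(flows = matrix(c(0, 0, 5, 0), 2),
              imports = c(5, 0), exports = c(0, 5),
              respiration = c(0, 0), throughflow = c(5, 5),
              types = c("producer", "consumer"), names = c("a", "b"))
  class(one) <- "flow_network"
  a <- ascendancy(one)
  expect_equal(a$ascendancy_percent, 100, tolerance = 1e-9)
})

test_that("pedigree scaffold scores user-supplied inputs", {
  sc <- matrix(c(0.7, 0.5, 0.6, 0.8, 0.4, 0.6), nrow = 3)
  p <- pedigree_index(sc)
  expect_equal(p$pedigree, mean(sc))
  expect_error(pedigree_index(matrix(c(0.5, 1.2), 1)), "0, 1")
})
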