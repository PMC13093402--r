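test_that("the same seed always generates the same web", {
  s <- synthetic_web_spec(seed = 42)
  expect_identical(generate_web(s), generate_web(s))
  s2 <- synthetic_web_spec(seed = 43)
  expect_false(identical(generate_web(s), generate_web(s2)))
})

test_that("generated webs are exactly stochastic and hit their EE targets", {
  for (sd in c(1, 7, 19)) {
    spec <- synthetic_web_spec(ee_target_range = c(0.3, 0.99), seed = sd)
    w <- generate_web(spec)
    cons <- w$groups$type == "consumer"
    expect_true(all(abs(colSums(w$diet)[cons] - 1) < 1e-12))
    bal <- balance_model(w)
    liv <- bal$stats$type != "detritus"
    expect_true(all(bal$stats$ee[liv] >= 0.3 - 1e-9 &
                      bal$stats$ee[liv] <= 0.99 + 1e-9))
    # the forward computation is its own oracle: solved EE == recorded EE
    expect_equal(bal$stats$ee[liv], attr(w, "truth")$ee[liv],
                 tolerance = 1e-10)
  }
})

test_that("spec invariants are checked at construction", {
  expect_error(synthetic_web_spec(ee_target_range = c(0, 1)))
  expect_error(synthetic_web_spec(diet_sparsity = 2))
  expect_error(synthetic_web_spec(n_producers = 0))
})

test_that("masking round-trips and keeps the system solvable", {
  w <- generate_web(synthetic_web_spec(seed = 5))
  cons <- which(w$groups$type == "consumer")
  wm <- mask_parameter(w, cons[2], "biomass")
  expect_true(is.na(wm$groups$biomass[cons[2]]))
  expect_false(is.na(wm$groups$ee[cons[2]]))
  back <- unmask_parameter(wm)
  expect_identical(back$groups, w$groups)
  expect_error(unmask_parameter(w), "no masked")
  expect_error(mask_parameter(w, "Detritus", "ee"), "detritus")
  expect_error(mask_parameter(w, "NoSuchGroup"), "unknown group")
})

test_that("hidden parameters are recovered across one hundred seeded webs", {
  worst <- 0
  n_checked <- 0
  for (sd in 1:100) {
    spec <- synthetic_web_spec(n_consumers = 4 + (sd %% 9),
                               tl_layers = 2 + (sd %% 2), seed = sd)
    w <- generate_web(spec)
    tr <- attr(w, "truth")
    bal0 <- balance_model(w)
    preyed <- which(w$groups$type == "consumer" &
                      bal0$stats$predation > 1e-6)
    if (length(preyed) == 0) next
    pick <- preyed[1 + (sd %% length(preyed))]
    # hide a biomass; the solver must find the recorded true value
    bm <- balance_model(mask_parameter(w, pick, "biomass"))
    worst <- max(worst, abs(bm$model$groups$biomass[pick] -
                              tr$biomass[pick]) / tr$biomass[pick])
    # hide an EE (the generator's default state): recovered too
    be <- balance_model(mask_parameter(w, pick, "ee"))
    worst <- max(worst, abs(be$stats$ee[pick] - tr$ee[pick]) / tr$ee[pick])
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 95)
  expect_lt(worst, 1e-6)
})

test_that("every index runs clean on arbitrary generated webs", {
  for (sd in c(2, 12, 77)) {
    w <- generate_web(synthetic_web_spec(n_consumers = 6 + sd %% 5,
                                         seed = sd))
    res <- run_full_analysis(w)
    expect_true(is.finite(res$summary$tst))
    expect_true(is.finite(res$summary$fci_percent))
    expect_true(is.finite(res$summary$ascendancy_percent))
    expect_true(all(is.finite(res$impacts$mti)))
    expect_true(res$summary$tst > 0)
  }
})

test_that("full analysis writes a complete, traceable report bundle", {
  out <- file.path(tempdir(), "limnoweb_run")
  unlink(out, recursive = TRUE)
  run_full_analysis(kaptai_model(), out_dir = out)
  expect_true(all(file.exists(file.path(out,
    c("group_statistics.csv", "lindeman_spine.csv",
      "transfer_efficiency.csv", "system_summary.csv", "mti.csv",
      "keystone.csv", "prey_overlap.csv", "predator_overlap.csv",
      "summary.json", "run_info.json")))))
  info <- jsonlite::read_json(file.path(out, "run_info.json"))
  expect_identical(info$package, "limnoweb")
  expect_true(!is.null(info$config_hash))
  # determinism: a second run writes byte-identical numeric outputs
  out2 <- file.path(tempdir(), "limnoweb_run2")
  unlink(out2, recursive = TRUE)
  run_full_analysis(kaptai_model(), out_dir = out2)
  f1 <- readLines(file.path(out, "system_summary.csv"))
  f2 <- readLines(file.path(out2, "system_summary.csv"))
  expect_identical(f1, f2)
  unlink(c(out, out2), recursive = TRUE)
})
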