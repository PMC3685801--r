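test_that("fixtures load by key with provenance, unknown keys fail helpfully", {
  f <- load_fixture("wheat_grain_normal")
  expect_equal(f$value[f$quantity == "se_pressure"], 1.11)
  expect_equal(f$value[f$quantity == "sink_pressure"], 0.12)
  t3 <- load_fixture("wheat_grain_table3")
  expect_equal(t3$value[t3$quantity == "viscosity"], 2e-9)
  expect_equal(t3$value[t3$quantity == "wall_thickness"], 500)
  expect_equal(t3$value[t3$quantity == "volume_import"], 10)
  expect_equal(t3$value[t3$quantity == "observed_pd"], 4.4e7)
  expect_true(all(nzchar(t3$provenance)))
  expect_error(load_fixture("nonexistent"), "available")
  expect_error(load_fixture("nonexistent"), class = "phloemanifold_unknown_fixture")
  # registry is rebuilt per call: fixtures cannot be mutated in place
  a <- load_fixture("wheat_grain_normal")
  a$value <- 0
  expect_equal(load_fixture("wheat_grain_normal")$value[1], 1.11)
})

test_that("bundle sampling is a pure function of seed and ranges", {
  expect_identical(sample_bundle(5), sample_bundle(5))
  expect_false(identical(sample_bundle(5), sample_bundle(6)))
  over <- sample_bundle(5, ranges = list(microchannel_radius_nm = c(1, 2)))
  expect_gte(over$microchannel_radius_nm, 1)
  expect_lte(over$microchannel_radius_nm, 2)
})

test_that("sampled bundles respect the published ranges and ordering constraints", {
  rg <- phloemanifold:::default_ranges()
  bundles <- dplyr::bind_rows(lapply(1:300, sample_bundle))
  expect_true(all(bundles$se_pressure_mpa > bundles$sink_turgor_mpa))
  expect_true(all(bundles$sucrose_se_mM > bundles$sucrose_parenchyma_mM))
  for (col in names(rg)) {
    key <- switch(col,
      se_pressure_mpa = "se_pressure_mpa", sink_turgor_mpa = "sink_turgor_mpa",
      sucrose_se_mM = "sucrose_se_mM", sucrose_parenchyma_mM = "sucrose_parenchyma_mM",
      microchannel_radius_nm = "microchannel_radius_nm", pd_count = "pd_count",
      import_ul_day = "import_ul_day"
    )
    expect_true(all(bundles[[key]] >= rg[[col]][1] & bundles[[key]] <= rg[[col]][2]),
      info = col
    )
  }
})

test_that("infeasible override ranges are rejected", {
  expect_error(
    sample_bundle(1, ranges = list(se_pressure_mpa = c(2, 1))),
    class = "phloemanifold_sampling_error"
  )
  expect_error(
    sample_bundle(1, ranges = list(se_pressure_mpa = c(0.01, 0.05))),
    class = "phloemanifold_sampling_error"
  )
})

test_that("every sampled bundle runs the full pipeline without error", {
  for (seed in 1:20) {
    b <- sample_bundle(seed)
    spec <- organ_import_spec(
      volume_import_ul_day = b$import_ul_day,
      observed_pd_count = b$pd_count,
      dP_mpa = b$se_pressure_mpa - b$sink_turgor_mpa
    )
    row <- pd_feasibility(b$microchannel_radius_nm, spec)
    expect_true(is.logical(row$feasible) && !is.na(row$feasible))

    cmp <- mode_comparison(
      b$microchannel_radius_nm,
      dC_mM = b$sucrose_se_mM - b$sucrose_parenchyma_mM,
      C_mM = b$sucrose_se_mM,
      dP_mpa = spec$dP_mpa,
      pairing = c(dC = b$sucrose_se_mM - b$sucrose_parenchyma_mM, C = b$sucrose_se_mM)
    )
    expect_true(cmp$dominant_mode %in% c("diffusion", "comparable", "bulk"))

    dec <- excision_decomposition(
      pressure_pair(b$se_pressure_mpa, b$sink_turgor_mpa), 19
    )
    expect_equal(dec$residual_fold * dec$dP_fold, 19, tolerance = 1e-12)
  }
})

test_that("network bundles are reproducible and solve cleanly", {
  expect_identical(make_network_bundle(3, 2), make_network_bundle(3, 2))
  expect_error(make_network_bundle(1, 0), class = "phloemanifold_sampling_error")
  for (seed in 1:5) {
    nb <- make_network_bundle(seed, 3)
    net <- build_manifold(
      nb$axial_conductances, nb$sink_conductances,
      nb$source_pressure_mpa, nb$sink_turgors_mpa
    )
    sol <- solve_steady_state(net)
    expect_lte(phloemanifold:::kirchhoff_residual(sol), 1e-9)
    expect_equal(sum(sol$sinks$partition_fraction), 1, tolerance = 1e-12)
  }
})
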