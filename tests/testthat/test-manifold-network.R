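# Independent oracle: assemble the full weighted Laplacian from the edge
# list with an incidence matrix and eliminate boundary nodes by dense solve.
oracle_pressures <- function(nodes, edges) {
  n <- nrow(nodes)
  B <- matrix(0, nrow(edges), n, dimnames = list(NULL, nodes$node))
  for (k in seq_len(nrow(edges))) {
    B[k, edges$from[k]] <- 1
    B[k, edges$to[k]] <- -1
  }
  L <- t(B) %*% diag(edges$conductance, nrow(edges)) %*% B
  fixed <- !is.na(nodes$boundary_pressure_mpa)
  p <- nodes$boundary_pressure_mpa
  if (any(!fixed)) {
    p[!fixed] <- solve(
      L[!fixed, !fixed, drop = FALSE],
      -L[!fixed, fixed, drop = FALSE] %*% p[fixed]
    )
  }
  stats::setNames(p, nodes$node)
}

test_that("series network follows the closed-form series conductance", {
  net <- build_manifold(1e8, 4e7, source_pressure_mpa = 1.2, sink_turgors_mpa = 0.2)
  sol <- solve_steady_state(net)
  g_series <- 1 / (1 / 1e8 + 1 / 4e7)
  expect_equal(sol$total_import_nm3_s, g_series * (1.2 - 0.2), tolerance = 1e-12)
  expect_equal(sol$sinks$partition_fraction, 1)
  expect_equal(nrow(sol$nodes), 3)
})

test_that("identical sinks split the import evenly", {
  # exactly symmetric star: both sinks hang from the same junction
  nodes <- tibble::tibble(
    node = c("source", "J1", "S1", "S2"),
    role = c("source", "junction", "sink", "sink"),
    boundary_pressure_mpa = c(1.0, NA, 0.2, 0.2)
  )
  edges <- tibble::tibble(
    from = c("source", "J1", "J1"),
    to = c("J1", "S1", "S2"),
    conductance = c(1e8, 1e6, 1e6),
    type = c("axial", "sink_interface", "sink_interface")
  )
  sol <- solve_steady_state(conductance_network(nodes, edges))
  expect_equal(sol$sinks$partition_fraction, c(0.5, 0.5), tolerance = 1e-12)

  # a comb with highly conductive axial segments approaches the even split
  comb <- solve_steady_state(build_manifold(rep(1e10, 2), rep(1e6, 2), 1.0, 0.2))
  expect_equal(comb$sinks$partition_fraction, c(0.5, 0.5), tolerance = 1e-4)
})

test_that("network construction rejects inconsistent or non-physical inputs", {
  expect_error(build_manifold(c(1, 2), 1, 1, 0.2), class = "phloemanifold_network_error")
  expect_error(build_manifold(1e8, 0, 1, 0.2), class = "phloemanifold_invalid_quantity")
  expect_error(build_manifold(numeric(), numeric(), 1, 0.2),
    class = "phloemanifold_network_error"
  )
  nodes <- tibble::tibble(
    node = c("a", "b"), role = c("source", "sink"),
    boundary_pressure_mpa = c(NA_real_, NA_real_)
  )
  edges <- tibble::tibble(from = "a", to = "b", conductance = 1, type = "sink_interface")
  expect_error(conductance_network(nodes, edges), class = "phloemanifold_network_error")
})

test_that("solver matches a dense brute-force solve on random small networks", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      n_free <- sample(1:4, 1)
      free_nodes <- paste0("J", seq_len(n_free))
      nodes <- tibble::tibble(
        node = c("source", free_nodes, "S1"),
        role = c("source", rep("junction", n_free), "sink"),
        boundary_pressure_mpa = c(runif(1, 0.8, 2), rep(NA_real_, n_free), runif(1, 0, 0.4))
      )
      # spanning path keeps the graph connected; extra random chords
      path <- tibble::tibble(
        from = nodes$node[-nrow(nodes)],
        to = nodes$node[-1]
      )
      all_pairs <- t(combn(nodes$node, 2))
      extra_idx <- sample(nrow(all_pairs), sample(0:3, 1))
      chords <- tibble::tibble(
        from = all_pairs[extra_idx, 1],
        to = all_pairs[extra_idx, 2]
      )
      edges <- dplyr::bind_rows(path, chords)
      edges$conductance <- 10^runif(nrow(edges), 4, 9)
      edges$type <- ifelse(edges$to == "S1" | edges$from == "S1", "sink_interface", "axial")
      net <- conductance_network(nodes, edges)
      sol <- solve_steady_state(net)
      expect_equal(
        stats::setNames(sol$nodes$pressure_mpa, sol$nodes$node),
        oracle_pressures(nodes, edges),
        tolerance = 1e-10
      )
    }
  })
})

test_that("Kirchhoff conservation holds at every interior node", {
  withr::with_seed(202, {
    for (rep in 1:10) {
      n <- sample(1:5, 1)
      net <- build_manifold(
        10^runif(n, 5, 10), 10^runif(n, 3, 7),
        runif(1, 0.8, 2.4), runif(n, 0.08, 0.33)
      )
      sol <- solve_steady_state(net)
      expect_lte(phloemanifold:::kirchhoff_residual(sol), 1e-9)
      expect_equal(sum(sol$sinks$partition_fraction), 1, tolerance = 1e-12)
    }
  })
})

test_that("raising one sink's conductance raises its share and no other's", {
  withr::with_seed(303, {
    base_g <- c(1e6, 2e6, 3e6)
    net0 <- build_manifold(rep(1e8, 3), base_g, 1.0, 0.2)
    f0 <- solve_steady_state(net0)$sinks$partition_fraction
    for (scale in c(1.5, 3, 10)) {
      g <- base_g
      g[2] <- g[2] * scale
      f <- solve_steady_state(build_manifold(rep(1e8, 3), g, 1.0, 0.2))$sinks$partition_fraction
      expect_gt(f[2], f0[2])
      expect_lte(f[1], f0[1])
      expect_lte(f[3], f0[3])
    }
  })
})

test_that("manifold limit: partitioning converges to conductance ratios and the axial drop vanishes", {
  sink_g <- c(1e5, 3e5, 6e5)
  g_share <- sink_g / sum(sink_g)
  ratios <- 10^(0:3) # axial/sink conductance ratio sweep 1 -> 1e3
  dev <- numeric(length(ratios))
  drop_frac <- numeric(length(ratios))
  for (i in seq_along(ratios)) {
    net <- build_manifold(rep(ratios[i] * sum(sink_g), 3), sink_g, 1.0, 0.2)
    sol <- solve_steady_state(net)
    regime <- manifold_regime_check(sol)
    dev[i] <- regime$partition_vs_conductance_deviation
    drop_frac[i] <- regime$axial_drop_fraction
  }
  expect_true(all(diff(dev) < 0))
  expect_true(all(diff(drop_frac) < 0))
  expect_lt(dev[length(dev)], 0.02)
  expect_lt(drop_frac[length(drop_frac)], 0.02)
  # at a ratio of 100 partitioning already tracks conductance shares; the
  # cumulative three-segment axial drop needs a higher ratio to fall under 2%
  net100 <- build_manifold(rep(100 * sum(sink_g), 3), sink_g, 1.0, 0.2)
  regime100 <- manifold_regime_check(solve_steady_state(net100))
  expect_lt(regime100$partition_vs_conductance_deviation, 0.02)
  expect_lt(regime100$axial_drop_fraction, 0.03)
  expect_lt(dev[4], 0.02)
  expect_lt(drop_frac[4], 0.02)
})

test_that("a wheat-grain-parameterised single sink reproduces the feasibility operating point", {
  row <- pd_feasibility(1.0)
  sink_g <- row$pd_required * row$microchannels_per_pd * hydraulic_conductance(1, 500)
  # axial path far more conductive than the plasmodesmal interface
  net <- build_manifold(1e4 * sink_g, sink_g, source_pressure_mpa = 1.0, sink_turgors_mpa = 0)
  sol <- solve_steady_state(net)
  expect_equal(sol$total_import_nm3_s, 11.6e13, tolerance = 1e-2)
  expect_equal(sol$sinks$partition_fraction, 1)
})

test_that("tidy and glance expose edges and regime metrics", {
  sol <- solve_steady_state(build_manifold(rep(1e9, 2), c(1e6, 3e6), 1, 0.2))
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("from", "to", "conductance", "flow_nm3_s") %in% names(td)))
  gl <- glance(sol)
  expect_identical(nrow(gl), 1L)
  expect_lt(gl$kirchhoff_residual, 1e-9)
  p <- autoplot(sol)
  expect_s3_class(p, "ggplot")
})
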