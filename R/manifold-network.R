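# Steady-state conductance-network formalisation of the high-pressure
# manifold: a source SE held at fixed pressure feeds a chain of axial
# sieve-tube segments; at each junction a plasmodesmal interface edge drains
# to a sink cell held at its turgor. Each edge obeys flow = L_o * dP; interior
# junction pressures solve the linear Kirchhoff system. In the manifold limit
# (axial conductance >> summed sink-interface conductance) the axial pressure
# drop vanishes and the partition of import between sinks converges to the
# ratio of their interface conductances.

#' Build a comb-topology manifold network
#'
#' Nodes are `source`, junctions `J1..Jn`, and sink terminals `S1..Sn`; axial
#' edges connect source -> J1 -> ... -> Jn and one sink-interface edge hangs
#' from each junction. Pressures are fixed at the source and at every sink
#' terminal; junction pressures are free.
#'
#' @param axial_conductances Conductances of the `n_sinks` axial segments,
#'   nm^3 s^-1 MPa^-1 (all > 0).
#' @param sink_conductances Conductances of the `n_sinks` plasmodesmal
#'   interface edges, nm^3 s^-1 MPa^-1 (all > 0).
#' @param source_pressure_mpa Source sieve-element pressure, MPa.
#' @param sink_turgors_mpa Sink-cell turgors, MPa; length `n_sinks` or 1
#'   (recycled).
#' @return An object of class `manifold_network`: tibbles of `nodes` (with
#'   boundary pressures) and `edges` (from, to, conductance, type).
#' @examples
#' build_manifold(rep(1e8, 3), rep(1e6, 3), 1.0, 0.2)
#' @export
build_manifold <- function(axial_conductances,
                           sink_conductances,
                           source_pressure_mpa = 1.0,
                           sink_turgors_mpa = 0.2) {
  n <- length(sink_conductances)
  if (n < 1 || length(axial_conductances) != n) {
    rlang::abort(
      "need one axial segment per sink: length(axial_conductances) must equal length(sink_conductances) >= 1",
      class = "phloemanifold_network_error"
    )
  }
  check_positive_finite(axial_conductances, "axial conductance")
  check_positive_finite(sink_conductances, "sink interface conductance")
  check_nonnegative_finite(source_pressure_mpa, "source pressure (MPa)")
  check_nonnegative_finite(sink_turgors_mpa, "sink turgor (MPa)")
  sink_turgors_mpa <- rep_len(sink_turgors_mpa, n)

  junctions <- paste0("J", seq_len(n))
  sinks <- paste0("S", seq_len(n))
  nodes <- tibble::tibble(
    node = c("source", junctions, sinks),
    role = c("source", rep("junction", n), rep("sink", n)),
    boundary_pressure_mpa = c(source_pressure_mpa, rep(NA_real_, n), sink_turgors_mpa)
  )
  edges <- tibble::tibble(
    from = c("source", junctions[-n], junctions),
    to = c(junctions, sinks),
    conductance = c(axial_conductances, sink_conductances),
    type = c(rep("axial", n), rep("sink_interface", n))
  )
  structure(list(nodes = nodes, edges = edges), class = "manifold_network")
}

#' Build an arbitrary conductance network
#'
#' General constructor for networks that are not simple combs: any connected
#' set of nodes and conductance edges with pressure fixed on at least one
#' node. Edges of type `"sink_interface"` define the sinks over which
#' partition fractions are computed.
#'
#' @param nodes A data frame with columns `node`, `role` (`"source"`,
#'   `"junction"` or `"sink"`) and `boundary_pressure_mpa` (`NA` for free
#'   nodes).
#' @param edges A data frame with columns `from`, `to`, `conductance` (> 0)
#'   and `type` (`"axial"` or `"sink_interface"`).
#' @return A `manifold_network`.
#' @examples
#' nodes <- tibble::tibble(
#'   node = c("source", "J1", "S1"), role = c("source", "junction", "sink"),
#'   boundary_pressure_mpa = c(1, NA, 0.2)
#' )
#' edges <- tibble::tibble(
#'   from = c("source", "J1"), to = c("J1", "S1"),
#'   conductance = c(1e8, 1e6), type = c("axial", "sink_interface")
#' )
#' solve_steady_state(conductance_network(nodes, edges))
#' @export
conductance_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(
    all(c("node", "role", "boundary_pressure_mpa") %in% names(nodes)),
    all(c("from", "to", "conductance", "type") %in% names(edges))
  )
  if (anyDuplicated(nodes$node)) {
    rlang::abort("duplicate node labels", class = "phloemanifold_network_error")
  }
  if (!all(c(edges$from, edges$to) %in% nodes$node)) {
    rlang::abort("edge endpoints must be declared nodes", class = "phloemanifold_network_error")
  }
  check_positive_finite(edges$conductance, "edge conductance")
  if (!any(!is.na(nodes$boundary_pressure_mpa))) {
    rlang::abort("at least one node needs a fixed boundary pressure",
      class = "phloemanifold_network_error"
    )
  }
  structure(list(nodes = nodes, edges = edges), class = "manifold_network")
}

#' @export
print.manifold_network <- function(x, ...) {
  n_sink <- sum(x$nodes$role == "sink")
  cat(sprintf(
    "<manifold_network> %d nodes, %d edges, %d sink(s)\n",
    nrow(x$nodes), nrow(x$edges), n_sink
  ))
  invisible(x)
}

#' Solve a manifold network for steady-state pressures and flows
#'
#' Direct linear nodal analysis: conservation at every free (junction) node
#' with `flow = conductance * (P_from - P_to)` on each edge, boundary
#' pressures fixed. Deterministic; node order is the construction order.
#'
#' @param network A [build_manifold()] network.
#' @return An object of class `manifold_flow`: `nodes` (with solved
#'   `pressure_mpa`), `edges` (with `flow_nm3_s`), `sinks` (per-sink import
#'   and `partition_fraction`, summing to 1), `axial_drop_mpa` (source
#'   pressure minus last junction pressure), and `total_import_nm3_s`.
#' @examples
#' solve_steady_state(build_manifold(rep(1e8, 2), rep(1e6, 2), 1, 0.2))
#' @export
solve_steady_state <- function(network) {
  stopifnot(inherits(network, "manifold_network"))
  nodes <- network$nodes
  edges <- network$edges
  free <- which(is.na(nodes$boundary_pressure_mpa))
  fixed <- which(!is.na(nodes$boundary_pressure_mpa))
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$node)

  # weighted graph Laplacian over all nodes
  n_all <- nrow(nodes)
  lap <- matrix(0, n_all, n_all)
  for (k in seq_len(nrow(edges))) {
    i <- idx[[edges$from[k]]]
    j <- idx[[edges$to[k]]]
    g <- edges$conductance[k]
    lap[i, i] <- lap[i, i] + g
    lap[j, j] <- lap[j, j] + g
    lap[i, j] <- lap[i, j] - g
    lap[j, i] <- lap[j, i] - g
  }
  p <- nodes$boundary_pressure_mpa
  if (length(free) > 0) {
    a <- lap[free, free, drop = FALSE]
    b <- -lap[free, fixed, drop = FALSE] %*% p[fixed]
    sol <- tryCatch(
      solve(a, b),
      error = function(e) rlang::abort(
        paste0("singular conservation system: ", conditionMessage(e)),
        class = "phloemanifold_solver_error"
      )
    )
    p[free] <- as.numeric(sol)
  }
  nodes$pressure_mpa <- p
  edges$flow_nm3_s <- edges$conductance * (p[idx[edges$from]] - p[idx[edges$to]])

  sink_edges <- edges[edges$type == "sink_interface", ]
  total <- sum(sink_edges$flow_nm3_s)
  sinks <- tibble::tibble(
    sink = sink_edges$to,
    conductance = sink_edges$conductance,
    import_nm3_s = sink_edges$flow_nm3_s,
    partition_fraction = sink_edges$flow_nm3_s / total
  )
  junction_p <- p[nodes$role == "junction"]
  source_p <- nodes$pressure_mpa[match("source", nodes$role)]
  axial_drop <- if (length(junction_p) > 0) source_p - junction_p[length(junction_p)] else 0
  structure(
    list(
      nodes = nodes,
      edges = edges,
      sinks = sinks,
      axial_drop_mpa = axial_drop,
      total_import_nm3_s = total
    ),
    class = "manifold_flow"
  )
}

#' @export
print.manifold_flow <- function(x, ...) {
  cat(sprintf(
    "<manifold_flow> total import %.4g nm^3/s, axial drop %.4g MPa\n",
    x$total_import_nm3_s, x$axial_drop_mpa
  ))
  print(x$sinks)
  invisible(x)
}

#' Tidy the edge flows of a solved manifold network
#'
#' @param x A `manifold_flow`.
#' @param ... Unused.
#' @return A tibble of edges with conductance, type and solved flow.
#' @importFrom generics tidy
#' @export
tidy.manifold_flow <- function(x, ...) x$edges

#' One-row summary of a solved manifold network
#'
#' @param x A `manifold_flow`.
#' @param ... Unused.
#' @return A tibble with `n_sinks`, `total_import_nm3_s`, `axial_drop_mpa`,
#'   `axial_drop_fraction`, `partition_deviation`, and the worst interior
#'   conservation residual `kirchhoff_residual` (relative).
#' @importFrom generics glance
#' @export
glance.manifold_flow <- function(x, ...) {
  regime <- manifold_regime_check(x)
  tibble::tibble(
    n_sinks = nrow(x$sinks),
    total_import_nm3_s = x$total_import_nm3_s,
    axial_drop_mpa = x$axial_drop_mpa,
    axial_drop_fraction = regime$axial_drop_fraction,
    partition_deviation = regime$partition_vs_conductance_deviation,
    kirchhoff_residual = kirchhoff_residual(x)
  )
}

# max relative net-flow imbalance over interior (junction) nodes
kirchhoff_residual <- function(solution) {
  nodes <- solution$nodes
  edges <- solution$edges
  res <- purrr::map_dbl(nodes$node[nodes$role == "junction"], function(nd) {
    inflow <- sum(edges$flow_nm3_s[edges$to == nd])
    outflow <- sum(edges$flow_nm3_s[edges$from == nd])
    scale <- max(abs(inflow), abs(outflow), .Machine$double.xmin)
    abs(inflow - outflow) / scale
  })
  max(c(res, 0))
}

#' Check how closely a solved network operates in the manifold regime
#'
#' The high-pressure manifold regime has two signatures: the axial pressure
#' drop is a small fraction of the available source-to-sink differential, and
#' each sink's partition fraction tracks its share of the summed interface
#' conductance. Both deviations shrink toward zero as the axial/sink
#' conductance ratio grows.
#'
#' @param solution A solved `manifold_flow`.
#' @return A list: `axial_drop_fraction` (axial drop over source pressure
#'   minus mean sink turgor) and `partition_vs_conductance_deviation` (max
#'   over sinks of |partition fraction - normalised conductance|).
#' @examples
#' net <- build_manifold(rep(1e9, 3), c(1e6, 2e6, 3e6), 1, 0.2)
#' manifold_regime_check(solve_steady_state(net))
#' @export
manifold_regime_check <- function(solution) {
  stopifnot(inherits(solution, "manifold_flow"))
  nodes <- solution$nodes
  source_p <- nodes$pressure_mpa[nodes$role == "source"]
  mean_turgor <- mean(nodes$boundary_pressure_mpa[nodes$role == "sink"])
  g_norm <- solution$sinks$conductance / sum(solution$sinks$conductance)
  list(
    axial_drop_fraction = solution$axial_drop_mpa / (source_p - mean_turgor),
    partition_vs_conductance_deviation =
      max(abs(solution$sinks$partition_fraction - g_norm))
  )
}

#' Plot partition fractions against normalised sink conductances
#'
#' Visual check of the manifold claim that partitioning is set by relative
#' plasmodesmal conductances: points on the identity line indicate the
#' manifold regime.
#'
#' @param object A `manifold_flow`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.manifold_flow <- function(object, ...) {
  df <- dplyr::mutate(
    object$sinks,
    conductance_share = .data$conductance / sum(.data$conductance)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conductance_share, y = .data$partition_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "sink share of summed interface conductance",
      y = "partition fraction of phloem import",
      title = "Partitioning vs relative plasmodesmal conductance"
    ) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
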