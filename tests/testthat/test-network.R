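single_node_spec <- function(u, w = 1, tau = 0.1) {
  network_spec(
    nodes = list(U = list(), A = list(tau = tau)),
    reactions = list(list(sources = list(list(id = "U", sign = "activating")),
                          target = "A", w = w)),
    inputs = list(U = matrix(c(0, u), 1, 2))
  )
}

test_that("normalized Hill activation is pinned at 0, EC50 and 1", {
  p <- hill_params()
  expect_equal(p$w, 1)
  expect_equal(p$ec50, 0.5)
  expect_equal(p$n, 1.223)
  expect_lt(abs(normalized_hill(0, p)), 1e-9)
  expect_lt(abs(normalized_hill(1, p) - 1), 1e-9)
  expect_lt(abs(normalized_hill(0.5, p) - 0.5), 1e-9)
  # monotone non-decreasing on a grid
  grid <- normalized_hill(seq(0, 1, by = 0.01), p)
  expect_true(all(diff(grid) >= 0))
  expect_error(normalized_hill(1.2, p), "outside")
  expect_error(normalized_hill(-0.2, p), "outside")
  expect_error(hill_params(ec50 = 0.9, n = 3), "ec50")
  expect_error(hill_params(w = 2), "w")
})

test_that("continuous gates implement noisy-OR and product-AND", {
  for (a in c(0, 0.5, 1)) {
    expect_equal(gate_combine(c(0, a), "OR"), a)
    expect_equal(gate_combine(c(1, a), "AND"), a)
  }
  set.seed(2)
  a <- runif(3)
  expect_equal(gate_combine(a, "OR"), 1 - prod(1 - a))
  expect_equal(gate_combine(a, "AND"), prod(a))
  expect_error(gate_combine(numeric(0)), "empty")
  expect_error(gate_combine(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("network specs validate node references and duplicates", {
  expect_error(
    network_spec(list(A = list()),
                 list(list(sources = list(list(id = "B", sign = "activating")),
                           target = "A"))),
    "not a declared node")
  expect_error(
    network_spec(list(A = list(), B = list()),
                 list(list(sources = list(list(id = "A", sign = "activating")),
                           target = "nope"))),
    "not a declared node")
  rx <- list(sources = list(list(id = "A", sign = "activating")),
             target = "B")
  expect_error(network_spec(list(A = list(), B = list()), list(rx, rx)),
               "duplicate")
})

test_that("a single node under saturating input reaches its analytic steady state", {
  sim <- simulate_network(single_node_spec(u = 1), t_end = 20)
  expect_lt(abs(sim$final_state[["A"]] - 1), 1e-4)
  # default initialization: everything starts at 0
  expect_equal(unname(sim$trajectories[1L, "A"]), 0)
  # zero input keeps the off-state absorbing
  sim0 <- simulate_network(single_node_spec(u = 0), t_end = 5)
  expect_true(all(abs(sim0$trajectories[, "A"]) < 1e-12))
  # analytic limit y* = ymax * f(w * u) across the input grid
  p <- hill_params()
  for (u in c(0, 0.25, 0.5, 0.75, 1)) {
    sim_u <- simulate_network(single_node_spec(u = u), t_end = 20)
    expect_lt(abs(sim_u$final_state[["A"]] - normalized_hill(u, p)), 1e-6)
  }
})

test_that("adaptive trajectories match a fixed-step RK4 reference", {
  # two-node chain
  chain <- network_spec(
    nodes = list(U = list(), A = list(tau = 0.5), B = list(tau = 1)),
    reactions = list(
      list(sources = list(list(id = "U", sign = "activating")), target = "A"),
      list(sources = list(list(id = "A", sign = "activating")), target = "B")
    ),
    inputs = list(U = matrix(c(0, 0.7), 1, 2))
  )
  out_t <- seq(0, 5, by = 0.5)
  sim <- simulate_network(chain, t_end = 5, n_out = 11L)
  ref <- rk4_trajectories(chain, t_end = 5, dt = 1e-3, out_times = out_t)
  expect_lt(max(abs(sim$trajectories[, c("A", "B")] - ref[, c("A", "B")])),
            1e-4)
  # full Nrg1 network
  spec <- build_nrg1_network()
  out_t2 <- seq(0, 10, by = 1)
  sim2 <- simulate_network(spec, t_end = 10, n_out = 11L)
  ref2 <- rk4_trajectories(spec, t_end = 10, dt = 1e-3, out_times = out_t2)
  nodes <- colnames(ref2)
  expect_lt(max(abs(sim2$trajectories[, nodes] - ref2)), 1e-4)
})

test_that("trajectories stay within [0, ymax] under bounded inputs", {
  sim <- simulate_network(build_nrg1_network(), t_end = 20)
  expect_true(all(sim$trajectories >= -1e-6))
  expect_true(all(sim$trajectories <= 1 + 1e-6))
  capped <- apply_perturbation(build_nrg1_network(), "Akt", "ymax_scale", 0.4)
  simc <- simulate_network(capped, t_end = 20)
  expect_true(all(simc$trajectories[, "Akt"] <= 0.4 + 1e-6))
})

test_that("steady-state ERBB activity is monotone in the Nrg1 input weight", {
  erbb_ss <- vapply(seq(0, 1, length.out = 11L), function(w) {
    spec <- build_nrg1_network(treatment = TRUE, treated_weight = w)
    # ERBB depends only on Nrg1; a short chain suffices for steady state
    simulate_network(spec, t_end = 20, n_out = 50L)$final_state[["ERBB"]]
  }, numeric(1L))
  expect_true(all(diff(erbb_ss) >= -1e-9))
})

test_that("the Nrg1 step drives transient p38 and slowly rising Akt", {
  sim <- simulate_network(build_nrg1_network(), t_end = 20)
  p38 <- trajectory_summary(sim, "p38")
  akt <- trajectory_summary(sim, "Akt")
  # p38 peaks at an interior time, then declines by more than 10%
  expect_gt(p38$peak_time, 0)
  expect_lt(p38$peak_time, max(sim$times))
  expect_lt(p38$final_over_peak, 0.9)
  # Akt rises slowly: half-max later than the p38 peak, non-decreasing after
  # its initial transient
  expect_gt(akt$t_half_max, p38$peak_time)
  akt_traj <- sim$trajectories[, "Akt"]
  late <- akt_traj[sim$times > 1]
  expect_true(all(diff(late) >= -1e-8))
  # removing the DUSP brake makes p38 monotone non-decreasing
  no_fb <- build_nrg1_network()
  keep <- vapply(no_fb$reactions, function(rx) {
    !(rx$target == "p38" &&
        any(vapply(rx$sources, function(s) s$id == "DUSP", logical(1L))))
  }, logical(1L))
  ablated <- network_spec(
    nodes = no_fb$nodes,
    reactions = c(no_fb$reactions[keep],
                  list(list(sources = list(list(id = "Ras",
                                                sign = "activating")),
                            target = "p38"))),
    inputs = no_fb$inputs
  )
  sim_ab <- simulate_network(ablated, t_end = 20)
  expect_true(all(diff(sim_ab$trajectories[, "p38"]) >= -1e-8))
})

test_that("baseline Nrg1 input keeps the network near its off-state", {
  sim <- simulate_network(build_nrg1_network(treatment = FALSE), t_end = 20)
  expect_true(all(sim$final_state < 0.2))
})

test_that("in-silico kinase inhibition reproduces the pathway dissection", {
  spec <- build_nrg1_network()
  # identity perturbation leaves the spec untouched
  expect_identical(apply_perturbation(spec, "PI3K", "ymax_scale", 1), spec)
  expect_identical(apply_perturbation(spec, "PI3K", "weight_scale", 1), spec)
  expect_error(apply_perturbation(spec, "nosuch", "ymax_scale", 0),
               "unknown node")
  panel <- run_perturbation_panel(
    spec,
    list(PI3Ki = list(node = "PI3K", mode = "ymax_scale", factor = 0),
         p38i = list(node = "p38", mode = "ymax_scale", factor = 0))
  )
  ss <- function(cond, out) {
    panel$steady_state[panel$condition == cond & panel$output == out]
  }
  # PI3K knockout lowers both elongation and area
  expect_lt(ss("PI3Ki", "Elongation"), ss("base", "Elongation"))
  expect_lt(ss("PI3Ki", "Area"), ss("base", "Area"))
  # p38 knockout lowers area but spares elongation (< 5% of dynamic range)
  expect_lt(ss("p38i", "Area"), ss("base", "Area"))
  expect_lt(abs(ss("p38i", "Elongation") - ss("base", "Elongation")),
            0.05 * ss("base", "Elongation"))
  # weight_scale attenuates incoming reactions
  damp <- apply_perturbation(spec, "ERBB", "weight_scale", 0.5)
  w <- vapply(damp$reactions, function(rx) rx$hill$w, numeric(1L))
  tg <- vapply(damp$reactions, `[[`, character(1L), "target")
  expect_equal(unname(w[tg == "ERBB"]), 0.5)
  expect_true(all(w[tg != "ERBB"] == 1))
})

test_that("network specs round-trip through JSON and the text grammar", {
  spec <- build_nrg1_network()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_network_json(spec, tmp)
  back <- read_network_json(tmp)
  expect_equal(back, spec)
  # text grammar builds the same topology
  lines <- c(
    "# Nrg1 core topology",
    "=> Nrg1",
    "Nrg1 => ERBB",
    "ERBB => PI3K",
    "PI3K => Akt",
    "Akt => Elongation",
    "Akt => Area",
    "ERBB => Ras",
    "!DUSP & Ras => p38",
    "p38 => Area",
    "p38 => DUSP"
  )
  parsed <- parse_reaction_lines(
    lines,
    input_weights = c(Nrg1 = 0.3),
    node_params = lapply(spec$nodes, function(nd) nd)
  )
  expect_setequal(names(parsed$nodes), names(spec$nodes))
  expect_length(parsed$reactions, length(spec$reactions))
  p38_rx <- Filter(function(rx) rx$target == "p38", parsed$reactions)[[1L]]
  signs <- vapply(p38_rx$sources, `[[`, character(1L), "sign")
  ids <- vapply(p38_rx$sources, `[[`, character(1L), "id")
  expect_identical(signs[ids == "DUSP"], "inhibiting")
  expect_identical(signs[ids == "Ras"], "activating")
  sim_a <- simulate_network(spec, t_end = 5, n_out = 21L)
  sim_b <- simulate_network(parsed, t_end = 5, n_out = 21L)
  expect_equal(sim_a$trajectories[, names(spec$nodes)],
               sim_b$trajectories[, names(spec$nodes)], tolerance = 1e-8)
  expect_error(parse_reaction_lines("Akt -> Area"), "malformed")
})
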