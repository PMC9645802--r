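test_that("stochastic rate conversion: identity, dimensional bridge, scaling", {
  expect_identical(stochastic_rate_constant(10, 1), 10)
  # 1000 (uM s)^-1 in 1 um^3: 1e9 M^-1 s^-1 / (N_A * 1e-15 L)
  c2 <- stochastic_rate_constant(1000, 2, 1e-18, "per_uM_s")
  expect_equal(c2, 1e9 / (6.02214076e23 * 1e-15), tolerance = 1e-12)
  expect_equal(c2, 1.6605, tolerance = 1e-4)
  # doubling the volume halves c
  c_half <- stochastic_rate_constant(1, 2, 2e-18, "per_uM_s")
  expect_equal(c_half * 2, stochastic_rate_constant(1, 2, 1e-18, "per_uM_s"))
  expect_error(stochastic_rate_constant(1, 3, 1e-18, "per_M_s"), "order")
  expect_error(stochastic_rate_constant(1, 2, NULL, "per_M_s"), "volume")
  expect_error(reaction(c(), c(A = 1), 1), "order")
  expect_error(reaction(c(A = 1, B = 1, C = 1), c(), 1), "order 2")
})

test_that("largest-remainder rounding conserves totals without bias", {
  set.seed(5)
  for (i in 1:50) {
    x <- stats::runif(sample(1:30, 1), 0, 20)
    r <- largest_remainder_round(x)
    expect_identical(sum(r), as.integer(round(sum(x))))
    expect_true(all(abs(r - x) <= 1))
  }
})

test_that("ten-species benchmark binds to 8 unidirectional processes per tet", {
  fx <- fixture_simple_model(scale = 1, resolution = c(2, 2, 4))
  mesh <- fx$build_mesh()
  b <- bind_model(fx$model, mesh)
  expect_identical(b$n_proc, 8L * nrow(mesh$tets))
  # printed table values at scale 1
  init <- fx$model$initial$comp
  expect_identical(unname(init["J"]), 10000)
  expect_identical(unname(init["A"]), 1000)
  expect_equal(sum(init), 55000)
  expect_equal(fx$model$diffusion[[10]]$D, 10e-12)
  fx001 <- fixture_simple_model(scale = 0.01)
  expect_identical(unname(fx001$model$initial$comp["A"]), 10)
})

test_that("two-tet toy binds to 10 processes: 3 volume per tet + 4 surface", {
  fx <- fixture_ghk_toy()
  b <- bind_model(fx$model, fx$mesh)
  expect_identical(b$n_proc, 10L)
  lab <- b$procs$label
  expect_identical(sum(startsWith(lab, "rxn:")), 6L)
  expect_identical(sum(startsWith(lab, "srxn:")), 2L)
  expect_identical(sum(startsWith(lab, "ghk")), 2L)
  expect_true(all(b$procs$is_tri[startsWith(lab, "srxn:") |
                                 startsWith(lab, "ghk")]))
})

test_that("an empty model binds to zero processes on any mesh", {
  mesh <- two_tet_mesh()
  b <- bind_model(sim_model(species = character(0)), mesh)
  expect_identical(b$n_proc, 0L)
  s <- simulation(b, seed = 1)
  run(s, 0.5)
  expect_equal(s$t, 0.5)
})

test_that("binding is deterministic and idempotent", {
  fx <- fixture_simple_model(scale = 0.1, resolution = c(2, 1, 2))
  mesh <- fx$build_mesh()
  b1 <- bind_model(fx$model, mesh)
  b2 <- bind_model(fx$model, mesh)
  expect_identical(b1$procs$r1, b2$procs$r1)
  expect_identical(b1$procs$cbase, b2$procs$cbase)
  expect_identical(b1$procs$eff, b2$procs$eff)
})

test_that("binding rejects unknown tags and undeclared species", {
  mesh <- two_tet_mesh()
  expect_error(
    bind_model(sim_model("A", reactions = list(
      reaction(c(A = 1), c(), 1, compartment = "nope"))), mesh),
    "unknown compartment tag 'nope'")
  expect_error(
    bind_model(sim_model("A", reactions = list(
      reaction(c(B = 1), c(A = 1), 1))), mesh),
    "undeclared species: B")
  expect_error(
    bind_model(sim_model("A", reactions = list(
      surface_reaction(lhs_tet = c(A = 1), rhs_tri = c(A = 1), rate = 1,
                       patch = "not_a_patch"))), mesh),
    "unknown patch tag")
})

test_that("channel density conversion conserves patch totals", {
  fx <- fixture_rallpack3(g_single = 4e-12, axial_segments = 20)
  b <- bind_model(fx$model, fx$mesh)
  ms <- b$measures
  scale <- unname(fx$mesh$surface_scale["memb"])
  area <- sum(ms$tri_areas) * scale
  for (cn in c("Na", "K")) {
    dens <- fx$model$membranes[[1]]$channel_densities[[cn]]
    tot <- sum(b$membranes$memb$channels[[cn]]$counts)
    expect_identical(tot, as.integer(round(dens * area)))
    expect_true(tot >= floor(dens * area) && tot <= ceiling(dens * area))
  }
  # 20 pS has 5x fewer channels than 4 pS
  fx20 <- fixture_rallpack3(g_single = 20e-12, axial_segments = 20)
  b20 <- bind_model(fx20$model, fx20$mesh)
  n4 <- sum(b$membranes$memb$channels$Na$counts)
  n20 <- sum(b20$membranes$memb$channels$Na$counts)
  expect_equal(n4 / n20, 5, tolerance = 1e-3)
})
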