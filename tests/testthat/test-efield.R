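test_that("stiffness has the constant null space and matches dense assembly", {
  fx <- fixture_rallpack1(axial_segments = 10)
  b <- bind_model(fx$model, fx$mesh)
  V <- assemble_efield_system(b)
  n <- nrow(fx$mesh$vertices)
  expect_lt(max(abs(V$Kvol %*% rep(1, n))), 1e-12 * max(abs(V$Kvol)))
  expect_equal(as.matrix(V$Kvol), t(as.matrix(V$Kvol)), tolerance = 1e-12)

  # dense element-by-element assembly oracle on small random-ish meshes
  mesh <- two_tet_mesh()
  b2 <- bind_model(sim_model(character(0), membranes = list(
    membrane("memb", 0.01, 0.25, -0.065)), resistivity = 2), mesh)
  V2 <- assemble_efield_system(b2)
  ref <- matrix(0, 5, 5)
  for (e in seq_len(2)) {
    vs <- mesh$tets[e, ]
    P <- cbind(1, mesh$vertices[vs, ])
    C <- solve(P)                 # rows 2:4 of C are gradients of the hats
    grads <- t(C[2:4, ])
    vol <- abs(det(P)) / 6
    ref[vs, vs] <- ref[vs, vs] + (1 / 2) * vol * grads %*% t(grads)
  }
  expect_equal(as.matrix(V2$Kvol), ref, tolerance = 1e-12)
})

test_that("lumped capacitance equals Cm times the corrected membrane area", {
  fx <- fixture_rallpack1(axial_segments = 50)
  b <- bind_model(fx$model, fx$mesh)
  V <- assemble_efield_system(b)
  rho <- unname(fx$mesh$surface_scale["memb"])
  area <- sum(b$measures$tri_areas) * rho
  expect_equal(sum(V$Cvec), 0.01 * area, tolerance = 1e-12)
  expect_equal(sum(V$Gleak), 0.25 * area, tolerance = 1e-12)
})

test_that("GHK current: reversal zero, V->0 limit, empty-bath zero", {
  P <- 1e-19; z <- 2; cin <- 0.5; cout <- 2.0
  rt_f <- 8.31446262 * 293.15 / 96485.33212
  v_nernst <- -rt_f / z * log(cin / cout)   # c_in = c_out exp(-zFV/RT)
  expect_equal(ghk_current(P, z, v_nernst, cin, cout), 0, tolerance = 1e-25)
  # V -> 0 limit: P z F (c_in - c_out), checked against +-1 uV evaluations
  i0 <- P * z * 96485.33212 * (cin - cout)
  expect_equal(ghk_current(P, z, 0, cin, cout), i0, tolerance = 1e-12)
  expect_equal(ghk_current(P, z, 1e-6, cin, cout), i0, tolerance = 2e-4)
  expect_equal(ghk_current(P, z, -1e-6, cin, cout), i0, tolerance = 2e-4)
  expect_identical(ghk_current(P, z, seq(-0.1, 0.1, 0.05), 0, 0),
                   rep(0, 5))
})

test_that("zero currents leave a uniform potential unchanged", {
  mesh <- two_tet_mesh()
  b <- bind_model(sim_model(character(0), membranes = list(
    membrane("memb", 0.01, 0, 0))), mesh)
  V <- assemble_efield_system(b)
  V$v[] <- -0.07
  efield_step(V, numeric(b$n_state), 1e-5)
  expect_equal(V$v, rep(-0.07, length(V$v)), tolerance = 1e-9)
})

test_that("isopotential passive patch relaxes with tau = Cm/g to 0.1%", {
  mesh <- regular_tet_mesh(10e-6)
  b <- bind_model(sim_model(character(0), membranes = list(
    membrane("memb", 0.01, 0.25, -0.065))), mesh)
  V <- assemble_efield_system(b)
  v0 <- -0.040
  V$v[] <- v0
  dt <- 5e-6
  nstep <- 4000                       # 20 ms = tau/2
  for (i in seq_len(nstep)) efield_step(V, numeric(b$n_state), dt)
  tau <- 0.01 / 0.25
  expected <- -0.065 + (v0 + 0.065) * exp(-nstep * dt / tau)
  expect_lt(max(abs(V$v - expected)) / abs(expected - (-0.065)), 1e-3)
})

test_that("backward Euler stays bounded at 100x the default step", {
  mesh <- regular_tet_mesh(10e-6)
  b <- bind_model(sim_model(character(0), membranes = list(
    membrane("memb", 0.01, 0.25, -0.065))), mesh)
  V <- assemble_efield_system(b)
  V$v[] <- 0.2
  for (i in 1:1000) efield_step(V, numeric(b$n_state), 5e-4)
  expect_true(all(is.finite(V$v)))
  expect_lt(max(abs(V$v + 0.065)), 1e-3)   # 0.5 s >> tau: settled at rest
})

test_that("a model with channels but no membrane tag fails to assemble", {
  mesh <- tet_mesh(rbind(c(0, 0, 0), c(1e-6, 0, 0), c(0, 1e-6, 0),
                         c(0, 0, 1e-6)), matrix(1:4, 1))
  b <- bind_model(sim_model(character(0)), mesh)
  expect_error(assemble_efield_system(b), "no membrane")
})

test_that("HH gating: positivity, stationary open fraction, rate forms", {
  vgrid <- seq(-0.100, 0.060, by = 0.002)
  for (f in list(hh_alpha_m, hh_beta_m, hh_alpha_h, hh_beta_h,
                 hh_alpha_n, hh_beta_n)) {
    expect_true(all(f(vgrid) >= 0))
    expect_true(all(is.finite(f(vgrid))))
  }
  # removable singularities
  expect_equal(hh_alpha_m(-0.040), 1000, tolerance = 1e-9)
  expect_equal(hh_alpha_n(-0.055), 100, tolerance = 1e-9)

  # stationary open probability of the K channel at rest ~ n_inf^4:
  # birth-death stationary distribution of the 5-state ladder
  ch <- hh_gating_model(g_single = 4e-12)$K
  v <- -0.065
  an <- hh_alpha_n(v); bn <- hh_beta_n(v)
  n_inf <- an / (an + bn)
  # stationary distribution from the transition rates themselves
  rates_up <- vapply(0:3, function(k) (4 - k) * an, numeric(1))
  rates_dn <- vapply(1:4, function(k) k * bn, numeric(1))
  pi_un <- cumprod(c(1, rates_up / rates_dn))
  pi_st <- pi_un / sum(pi_un)
  expect_equal(pi_st[5], n_inf^4, tolerance = 1e-12)
  expect_equal(unname(ch$initial["n4"]), n_inf^4, tolerance = 1e-12)
  expect_equal(sum(ch$initial), 1, tolerance = 1e-12)
  na <- hh_gating_model()$Na
  expect_identical(length(na$states), 8L)
  expect_identical(na$open_states, "m3h1")
  expect_identical(length(ch$states), 5L)
})

test_that("deterministic-limit gating matches an ODE oracle within 1 mV", {
  det <- hh_membrane_deterministic(0.025, dt = 2.5e-7, i_density = 0.15)
  hh_ode <- function(t, y, p) {
    v <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    gna <- 1200 * m^3 * h; gk <- 360 * n^4
    dv <- (0.15 + gna * (0.05 - v) + gk * (-0.077 - v) +
             0.25 * (-0.065 - v)) / 0.01
    list(c(dv,
           hh_alpha_m(v) * (1 - m) - hh_beta_m(v) * m,
           hh_alpha_h(v) * (1 - h) - hh_beta_h(v) * h,
           hh_alpha_n(v) * (1 - n) - hh_beta_n(v) * n))
  }
  idx <- seq(1, nrow(det), by = 8)
  sol <- deSolve::lsoda(c(v = det$v[1], m = det$m[1], h = det$h[1],
                          n = det$n[1]),
                        det$time_s[idx], hh_ode, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sol[, "v"] - det$v[idx])), 1e-3)
  expect_gt(max(det$v), 0.040)   # it actually spikes
})
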