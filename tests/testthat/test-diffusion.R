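test_that("voxel coupling rates follow D*A/(V*h) with sealed boundaries", {
  mesh <- two_tet_mesh()
  b <- bind_model(sim_model("X", diffusion = list(
    diffusion_rule("X", 1e-9, "comp")), initial = list(comp = c(X = 1))),
    mesh)
  ms <- b$measures
  rates <- compute_diffusion_rates(ms, b$model$diffusion, b)
  sp <- rates$species$X
  A <- fmm_lookup(ms$nb_area, 0); h <- fmm_lookup(ms$nb_dist, 0)
  expect_equal(sp$d_tot[1], 1e-9 * A / (ms$volumes[1] * h))
  expect_equal(sp$d_tot[2], 1e-9 * A / (ms$volumes[2] * h))
  # linearity in D
  r2 <- compute_diffusion_rates(ms, list(diffusion_rule("X", 2e-9, "comp")), b)
  expect_equal(r2$species$X$d_tot, 2 * sp$d_tot)
  # boundary faces contribute nothing: each tet has exactly 1 neighbour
  expect_length(sp$slots, 1)
  # D = 0: no diffusive species
  r0 <- compute_diffusion_rates(ms, list(diffusion_rule("X", 0, "comp")), b)
  expect_length(r0$species, 0)
})

test_that("RD window rule: min(efield window, alpha / max rate)", {
  mesh <- two_tet_mesh()
  b <- bind_model(sim_model("X", diffusion = list(
    diffusion_rule("X", 1e-9, "comp")), initial = list(comp = c(X = 1))),
    mesh)
  rates <- compute_diffusion_rates(b$measures, b$model$diffusion, b)
  dmax <- rates$max_dtot
  # diffusion-limited
  expect_equal(select_rd_dt(rates, 1, 1), 1 / dmax)
  # efield-limited
  expect_equal(select_rd_dt(rates, 1e-9, 1), 1e-9)
  # equality case
  expect_equal(select_rd_dt(rates, 1 / dmax, 1), 1 / dmax)
  # alpha halves the window when diffusion-limited
  expect_equal(select_rd_dt(rates, 1, 0.5), 0.5 / dmax)
  # no diffusive species: window equals the efield window
  empty <- compute_diffusion_rates(b$measures, list(), b)
  expect_equal(select_rd_dt(empty, 2e-3, 1), 2e-3)
})

test_that("diffusion conserves every species exactly, for 1 and 4 ranks", {
  fx <- chain_fixture(8, D = 1e-9, N = 1234)
  for (R in c(1, 4)) {
    p <- partition_mesh(fx$mesh, R)
    b <- bind_model(fx$model, fx$mesh, p)
    s <- simulation(b, seed = 17)
    for (i in 1:30) {
      run(s, s$t + 2e-4)
      expect_identical(unname(species_totals(s$M, b)["X"]), 1234)
      expect_true(all(s$M$counts >= 0))
    }
  }
})

test_that("zero-length window is a no-op", {
  fx <- chain_fixture(4)
  b <- bind_model(fx$model, fx$mesh)
  s <- simulation(b, seed = 2)
  run(s, 0.001)
  before <- s$M$counts
  run(s, 0.001)
  expect_identical(s$M$counts, before)
})

test_that("two equal tets equilibrate to symmetric occupancy", {
  mesh <- generate_box_mesh(c(2e-6, 1e-6, 1e-6), c(2, 1, 1))
  model <- sim_model("X", diffusion = list(diffusion_rule("X", 1e-9, "comp")),
                     initial = list(comp = c(X = 1000)))
  b <- bind_model(model, mesh)
  s <- simulation(b, seed = 23, alpha_rd = 0.1)
  run(s, 0.01)
  half_idx <- b$vidx(seq_len(b$n_tet), "X")
  xs <- b$measures$barycenters[, 1]
  nsamp <- 400
  left <- numeric(nsamp)
  for (i in seq_len(nsamp)) {
    run(s, s$t + 1e-4)
    left[i] <- sum(s$M$counts[half_idx][xs < 1e-6])
  }
  # Binomial(1000, 1/2) stationary: mean within a generous MC band
  expect_lt(abs(mean(left) - 500), 3 * sqrt(250))
})

test_that("unequal volumes reach the volume-weighted stationary occupancy", {
  mesh <- two_tet_mesh()        # volumes 1:2
  model <- sim_model("X", diffusion = list(diffusion_rule("X", 1e-9, "comp")),
                     initial = list(comp = c(X = 400)))
  b <- bind_model(model, mesh)
  # small RD window: the windowed operator converges to the diffusion
  # master equation as alpha -> 0
  s <- simulation(b, seed = 29, alpha_rd = 0.05)
  run(s, 0.005)
  idx2 <- b$vidx(2, "X")
  nsamp <- 300
  occ <- numeric(nsamp)
  for (i in seq_len(nsamp)) {
    run(s, s$t + 2e-4)
    occ[i] <- s$M$counts[idx2]
  }
  frac <- b$measures$volumes[2] / sum(b$measures$volumes)
  expect_lt(abs(mean(occ) - 400 * frac), 6)
})

test_that("mean occupancy on a chain follows the rate-matrix exponential", {
  n <- 10
  N <- 1200
  fx <- chain_fixture(n, D = 1e-10, N = N)
  b <- bind_model(fx$model, fx$mesh)
  n_tet <- b$n_tet
  rates <- compute_diffusion_rates(b$measures, b$model$diffusion, b)
  sp <- rates$species$X
  # independent oracle: per-tet generator from the voxel-coupling formula,
  # propagated with the matrix exponential
  Q <- matrix(0, n_tet, n_tet)
  for (slot in sp$slots) {
    for (k in seq_along(slot$src)) {
      Q[slot$src[k], slot$dst_tet[k]] <- Q[slot$src[k], slot$dst_tet[k]] +
        slot$d_k[k]
    }
  }
  diag(Q) <- -rowSums(Q)
  t_obs <- 2e-3
  cell_of <- findInterval(b$measures$barycenters[, 1],
                          seq(0, n * 1e-6, by = 1e-6),
                          rightmost.closed = TRUE)
  in_cell1 <- which(cell_of == 1)       # 6 tets of the first box cell
  per_tet <- N / length(in_cell1)       # 200 molecules per tet, exact
  p0 <- numeric(n_tet)
  p0[in_cell1] <- per_tet
  pt <- as.numeric(p0 %*% as.matrix(Matrix::expm(Q * t_obs)))
  want <- vapply(seq_len(n), function(cc) sum(pt[cell_of == cc]), numeric(1))

  nrep <- 60
  occ <- matrix(0, nrep, n)
  for (r in seq_len(nrep)) {
    s <- simulation(b, seed = 4000 + r, alpha_rd = 0.05)
    s$M$counts[] <- 0
    s$M$counts[b$vidx(in_cell1, "X")] <- per_tet
    run(s, t_obs)
    for (cc in seq_len(n)) {
      occ[r, cc] <- sum(s$M$counts[b$vidx(which(cell_of == cc), "X")])
    }
  }
  got <- colMeans(occ)
  se <- apply(occ, 2, stats::sd) / sqrt(nrep)
  # 3 sigma on the replicate mean, plus a small allowance for the
  # windowed-operator discretization at alpha = 0.05
  expect_true(all(abs(got - want) < 3 * pmax(se, 1.5) + 0.02 * want + 1))
})

test_that("rank count does not bias diffusion outcomes (1 vs 4 ranks)", {
  fx <- chain_fixture(8, D = 5e-10, N = 300)
  ends <- function(R, seed) {
    p <- partition_mesh(fx$mesh, R)
    b <- bind_model(fx$model, fx$mesh, p)
    s <- simulation(b, seed = seed)
    run(s, 5e-4)
    xs <- b$measures$barycenters[, 1]
    sum(s$M$counts[b$vidx(which(xs < 4e-6), "X")])
  }
  n <- 200
  a1 <- vapply(seq_len(n), function(i) ends(1, i), numeric(1))
  a4 <- vapply(seq_len(n), function(i) ends(4, 7000 + i), numeric(1))
  expect_gt(cvm_2samp(a1, a4)$p_value, 0.001)
})
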