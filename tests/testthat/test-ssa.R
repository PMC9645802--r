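test_that("mass-action propensities: exhausted, bimolecular, symmetric pair", {
  mesh <- regular_tet_mesh()
  vol <- compute_measures(mesh)$volumes
  kc <- 2 / (6.02214076e23 * vol * 1e3)   # so that c == 2 after conversion
  model <- sim_model(c("A", "B", "C"),
    reactions = list(
      reaction(c(A = 1), c(B = 1), 10),
      reaction(c(A = 1, B = 1), c(C = 1), 1, "per_M_s"),
      reaction(c(A = 2), c(B = 1), 1, "per_M_s")),
    initial = list(comp = c(A = 0)))
  b <- bind_model(model, mesh)
  counts <- numeric(b$n_state)
  # A -> B with n_A = 0
  expect_equal(compute_propensity(b, counts, procs = 1L), 0)
  counts[b$vidx(1, "A")] <- 3
  counts[b$vidx(1, "B")] <- 4
  a <- compute_propensity(b, counts)
  expect_equal(a[1], 30)                       # c n
  c2 <- b$procs$cbase[2]
  expect_equal(a[2], c2 * 3 * 4)               # c nA nB
  counts[b$vidx(1, "A")] <- 5
  a <- compute_propensity(b, counts)
  c3 <- b$procs$cbase[3]
  expect_equal(a[3], c3 * 5 * 4 / 2)           # c n(n-1)/2
})

test_that("dependency graph equals brute-force stoichiometric recomputation", {
  set.seed(31)
  mesh <- two_tet_mesh()
  for (case in 1:20) {
    n_sp <- sample(2:4, 1)
    sp <- LETTERS[seq_len(n_sp)]
    n_rxn <- sample(2:5, 1)
    rxns <- lapply(seq_len(n_rxn), function(i) {
      lhs <- sample(sp, 1); rhs <- sample(setdiff(sp, lhs), 1)
      reaction(stats::setNames(1, lhs), stats::setNames(1, rhs),
               stats::runif(1, 0.5, 2))
    })
    b <- bind_model(sim_model(sp, reactions = rxns,
                              initial = list(comp = stats::setNames(
                                rep(10, n_sp), sp))), mesh)
    g <- build_dependency_graph(b)
    ref <- brute_force_dependencies(b)
    for (p in seq_len(b$n_proc)) {
      expect_identical(fmm_lookup(g$edges, p - 1L), ref[[p]])
    }
  }
})

test_that("disjoint-species reactions have no cross edges", {
  mesh <- regular_tet_mesh()
  b <- bind_model(sim_model(c("A", "B", "C", "D"),
    reactions = list(reaction(c(A = 1), c(B = 1), 1),
                     reaction(c(C = 1), c(D = 1), 1)),
    initial = list(comp = c(A = 5, C = 5))), mesh)
  g <- build_dependency_graph(b)
  expect_false(2L %in% fmm_lookup(g$edges, 0))
  expect_false(1L %in% fmm_lookup(g$edges, 1))
  comp <- split_components(g)
  expect_identical(length(unique(comp)), 2L)
})

test_that("two-tet toy graph splits into components of sizes 7 and 3", {
  fx <- fixture_ghk_toy()
  b <- bind_model(fx$model, fx$mesh)
  g <- build_dependency_graph(b)
  comp <- split_components(g)
  expect_identical(length(unique(comp)), 2L)
  expect_setequal(as.integer(table(comp)), c(7L, 3L))
})

test_that("fully connected and edgeless graphs split as expected", {
  mesh <- regular_tet_mesh()
  # cycle A->B->C->A: fully interdependent, 1 component
  b <- bind_model(sim_model(c("A", "B", "C"),
    reactions = list(reaction(c(A = 1), c(B = 1), 1),
                     reaction(c(B = 1), c(C = 1), 1),
                     reaction(c(C = 1), c(A = 1), 1)),
    initial = list(comp = c(A = 5))), mesh)
  expect_identical(length(unique(split_components(build_dependency_graph(b)))), 1L)
})

test_that("all-zero propensities advance time without events", {
  mesh <- regular_tet_mesh()
  b <- bind_model(sim_model(c("A", "B"),
    reactions = list(reaction(c(A = 1), c(B = 1), 5)),
    initial = list(comp = c(A = 0))), mesh)
  s <- simulation(b, seed = 1)
  run(s, 2)
  expect_identical(s$event_count, 0L)
  expect_equal(s$t, 2)
})

test_that("incremental propensity maintenance equals full recomputation", {
  fx <- fixture_ghk_toy()
  b <- bind_model(fx$model, fx$mesh)
  s <- simulation(b, seed = 12)
  for (i in 1:25) {
    run(s, s$t + 0.02)
    full <- compute_propensity(b, s$M$counts, s$ccur)
    expect_equal(s$a, full, tolerance = 1e-12)
  }
})

test_that("reversible pair reaches the binomial stationary law", {
  mesh <- regular_tet_mesh()
  N <- 1000
  b <- bind_model(ab_model(1, 1, N), mesh)
  s <- simulation(b, seed = 21)
  run(s, 4)   # ~8 relaxation times
  nsamp <- 500
  av <- numeric(nsamp)
  for (i in seq_len(nsamp)) {
    run(s, s$t + 0.1)    # ~100 independent relaxation times in total
    av[i] <- s$M$counts[b$vidx(1, "A")]
  }
  # stationary: Binomial(N, 1/2); samples weakly correlated (0.1 s apart,
  # relaxation time 0.5 s) -> Monte-Carlo bands on ~100 effective samples
  expect_lt(abs(mean(av) - N / 2), 5)
  expect_lt(abs(stats::var(av) - N / 4), 0.5 * N / 4)
})

test_that("pure decay matches the closed-form mean across replicates", {
  mesh <- regular_tet_mesh()
  n0 <- 1000
  model <- sim_model(c("A"),
                     reactions = list(reaction(c(A = 1), c(), 1)),
                     initial = list(comp = c(A = n0)))
  b <- bind_model(model, mesh)
  nrep <- 400
  left <- vapply(seq_len(nrep), function(i) {
    s <- simulation(b, seed = 1000 + i)
    run(s, 1)
    s$M$counts[b$vidx(1, "A")]
  }, numeric(1))
  mu <- n0 * exp(-1)
  sd1 <- sqrt(n0 * exp(-1) * (1 - exp(-1)))
  expect_lt(abs(mean(left) - mu), 3 * sd1 / sqrt(nrep))
})

test_that("NRM, direct method and component scheduling are distributionally equal", {
  mesh <- two_tet_mesh()
  model <- sim_model(c("A", "B", "C"),
    reactions = list(
      reaction(c(A = 1), c(B = 1), 2), reaction(c(B = 1), c(A = 1), 1),
      reaction(c(B = 1, C = 1), c(A = 1), 500, "per_uM_s"),
      reaction(c(A = 1), c(B = 1, C = 1), 1)),
    initial = list(comp = c(A = 50, B = 30, C = 20)))
  b <- bind_model(model, mesh)
  endA <- function(op, uc, seed) {
    s <- simulation(b, seed = seed, operator = op, use_components = uc)
    run(s, 0.5)
    species_totals(s$M, b)["A"]
  }
  nrep <- 250
  a_nrm <- vapply(seq_len(nrep), function(i) endA("nrm", FALSE, i), numeric(1))
  a_dir <- vapply(seq_len(nrep), function(i) endA("direct", FALSE, 5000 + i),
                  numeric(1))
  a_cmp <- vapply(seq_len(nrep), function(i) endA("nrm", TRUE, 9000 + i),
                  numeric(1))
  expect_gt(cvm_2samp(a_nrm, a_dir)$p_value, 0.001)
  expect_gt(cvm_2samp(a_nrm, a_cmp)$p_value, 0.001)
})

test_that("applied event times are nondecreasing and capped by the window", {
  fx <- fixture_ghk_toy()
  b <- bind_model(fx$model, fx$mesh)
  s <- simulation(b, seed = 3)
  s$event_log <- list()
  run(s, 0.3)
  log <- do.call(rbind, s$event_log)
  expect_true(all(diff(log[, 1]) >= 0))
  expect_true(all(log[, 1] <= 0.3))
})
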