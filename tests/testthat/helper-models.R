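# Shared builders for small test models.

# Two face-adjacent tetrahedra at micron scale (volumes 1:2).
two_tet_mesh <- function() {
  s <- 1e-6
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1)) * s
  tet_mesh(verts, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)),
           tris = rbind(c(1, 2, 3)),
           tet_tags = c("comp", "comp"), tri_tags = "memb")
}

# A regular tetrahedron with unit-ish edge (scaled to metres by `edge`).
regular_tet_mesh <- function(edge = 1e-6) {
  verts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    edge / (2 * sqrt(2))
  tet_mesh(verts, matrix(1:4, 1), tris = rbind(c(1, 2, 3)),
           tet_tags = "comp", tri_tags = "memb")
}

# Reversible isomerization A <=> B in one compartment.
ab_model <- function(kf = 1, kb = 1, n0 = 1000) {
  sim_model(species = c("A", "B"),
            reactions = list(reaction(c(A = 1), c(B = 1), kf),
                             reaction(c(B = 1), c(A = 1), kb)),
            initial = list(comp = c(A = n0)))
}

# A linear chain of n tets along z (box n x 1 x 1), one diffusive species.
chain_fixture <- function(n, D = 1e-9, N = 1000) {
  mesh <- generate_box_mesh(c(n * 1e-6, 1e-6, 1e-6), c(n, 1, 1))
  model <- sim_model(species = "X",
                     diffusion = list(diffusion_rule("X", D, "comp")),
                     initial = list(comp = c(X = N)))
  list(mesh = mesh, model = model)
}

# Reference multimap built from nested lists, for the container oracle.
reference_multimap <- function(keys, values, n_keys) {
  out <- vector("list", n_keys)
  for (i in seq_along(keys)) {
    k <- keys[i] + 1L
    out[[k]] <- c(out[[k]], values[i])
  }
  out
}

# Dense brute-force dependency edges from stoichiometry: p -> q iff p
# writes a state index that q reads as a reactant.
brute_force_dependencies <- function(bound) {
  n <- bound$n_proc
  edges <- vector("list", n)
  for (p in seq_len(n)) {
    writes <- bound$procs$eff[[p]][, 1]
    deps <- integer(0)
    for (q in seq_len(n)) {
      if (length(intersect(writes, bound$procs$reactants[[q]]))) {
        deps <- c(deps, q)
      }
    }
    edges[[p]] <- deps
  }
  edges
}
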