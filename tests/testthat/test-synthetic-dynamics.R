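# Brownian brush generator: reproducibility, conservation laws, drift

small <- function(...) {
  args <- list(n_chains = 4, beads_per_chain = 6, linker_beads = 2,
               n_steps = 300, save_stride = 50)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_params, args)
}

test_that("identical parameters and seed give bitwise-identical runs", {
  a <- simulate_brush(small(seed = 4))
  b <- simulate_brush(small(seed = 4))
  expect_identical(lapply(a$frames, `[[`, "positions"),
                   lapply(b$frames, `[[`, "positions"))
  c <- simulate_brush(small(seed = 5))
  expect_false(identical(a$frames[[2]]$positions, c$frames[[2]]$positions))
})

test_that("grafted anchor beads never move", {
  tr <- simulate_brush(small(seed = 2))
  anchors <- which(!duplicated(tr$topology$peptide_index) &
                     tr$topology$peptide_index > 0)
  p0 <- tr$frames[[1]]$positions[anchors, ]
  for (f in tr$frames) {
    expect_identical(f$positions[anchors, ], p0)
  }
})

test_that("quenched, force-free runs are static", {
  tr <- simulate_brush(small(seed = 1, temperature_factor = 0))
  for (f in tr$frames) {
    expect_equal(f$positions, tr$frames[[1]]$positions)
  }
})

test_that("quenched relaxation never increases the potential energy", {
  p <- small(seed = 3, temperature_factor = 0, interchain_attraction = 2,
             graft_spacing = 0.55, n_steps = 500)
  tr <- simulate_brush(p)
  e <- vapply(tr$frames, brush_energy, numeric(1), params = p)
  expect_lt(e[length(e)], e[1])  # something happened
  expect_true(all(diff(e) <= 1e-8))
})

test_that("beads stay within the grafted contour bound", {
  p <- small(seed = 6, n_steps = 600)
  tr <- simulate_brush(p)
  nb <- p$linker_beads + p$beads_per_chain
  bound <- p$bond_length * nb + 1  # anchor height + contour + stretch slack
  for (f in tr$frames) expect_lte(max(f$positions[, 3]), bound)
})

test_that("a single pulled free bead drifts by mobility * force * time", {
  # overdamped closed form: <dz> = -mu * (m a) * t, noise averages out
  mu <- 0.1; m <- 110; acc <- 0.01; nst <- 200; dt <- 0.1
  drift <- -mu * m * acc * nst * dt
  dz <- vapply(1:200, function(sd) {
    p <- synthetic_params(n_chains = 1, beads_per_chain = 1,
                          linker_beads = 0, grafted = FALSE,
                          bond_length = 50,  # start far above the wall
                          mobility = mu, bead_mass = m,
                          pull_acceleration = acc, timestep = dt,
                          n_steps = nst, save_stride = nst, seed = sd)
    tr <- simulate_brush(p)
    tr$frames[[2]]$positions[1, 3] - tr$frames[[1]]$positions[1, 3]
  }, numeric(1))
  se <- sd(dz) / sqrt(length(dz))
  expect_lt(abs(mean(dz) - drift), 3 * se)
})

test_that("pulling moves the peptide center of mass toward the surface", {
  p0 <- small(seed = 8, n_steps = 800)
  p1 <- p0; p1$pull_acceleration <- 0.01
  t0 <- simulate_brush(p0); t1 <- simulate_brush(p1)
  pep <- select_atoms(t0$topology, moiety = "peptide")
  z0 <- mean(t0$frames[[length(t0$frames)]]$positions[pep, 3])
  z1 <- mean(t1$frames[[length(t1$frames)]]$positions[pep, 3])
  expect_lt(z1, z0)
})

test_that("unstable settings raise the stability error", {
  expect_error(simulate_brush(small(seed = 1, temperature_factor = 1e4)),
               "unstable|displacement")
})

test_that("morphology pairs share topology and differ only in attraction", {
  base <- small(seed = 9)
  pair <- make_morphology_pair(base, eps_clustered = 2, eps_grid = 0.2)
  expect_identical(pair$clustered$topology, pair$grid$topology)
  expect_identical(length(pair$clustered$frames), length(pair$grid$frames))
  expect_identical(attr(pair$clustered, "params")$interchain_attraction, 2)
  expect_identical(attr(pair$grid, "params")$interchain_attraction, 0.2)
  expect_error(make_morphology_pair(base, 1, 2), "eps_clustered > eps_grid")
})

test_that("a fixed probe body stays rigid and carries spot labels", {
  pr <- probe_spec(depth = 2, width = 2, bead_spacing = 0.5, mode = "fixed")
  p <- small(seed = 10, probe = pr, n_steps = 300)
  tr <- simulate_brush(p)
  top <- tr$topology
  probe_at <- select_atoms(top, moiety = "protein")
  expect_gt(length(probe_at), 10)
  expect_setequal(unique(top$residue_name[probe_at]), active_spots()$name)
  for (f in tr$frames) {
    expect_identical(f$positions[probe_at, ],
                     tr$frames[[1]]$positions[probe_at, ])
  }
  # probe geometry: a cylinder of the requested size
  pp <- tr$frames[[1]]$positions[probe_at, ]
  expect_equal(diff(range(pp[, 3])), 2, tolerance = 0.5)
  expect_equal(diff(range(pp[, 1])), 2, tolerance = 0.5)
})

test_that("a z-diffusing probe moves vertically as one body", {
  pr <- probe_spec(depth = 2, width = 2, bead_spacing = 0.5,
                   mode = "zdiffuse", mobility = 0.05)
  p <- small(seed = 11, probe = pr, n_steps = 300)
  tr <- simulate_brush(p)
  probe_at <- select_atoms(tr$topology, moiety = "protein")
  first <- tr$frames[[1]]$positions[probe_at, ]
  last <- tr$frames[[length(tr$frames)]]$positions[probe_at, ]
  expect_identical(last[, 1:2], first[, 1:2])            # XY rigid
  dz <- last[, 3] - first[, 3]
  expect_gt(max(abs(dz)), 0)                             # it moved
  expect_lt(diff(range(dz)), 1e-12)                      # as one body
})

test_that("synthetic parameter validation catches bad values", {
  expect_error(synthetic_params(timestep = 0))
  expect_error(synthetic_params(pull_acceleration = -1))
  expect_error(synthetic_params(n_steps = 0))
  expect_error(synthetic_params(residue_labels = c("A", "B")))
})
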