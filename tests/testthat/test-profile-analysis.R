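# Density profiles, threshold distances, centroid shifts, convergence

test_that("a single atom yields the definitional slice density", {
  top <- topology(atom_name = "CA", residue_name = "ALA", residue_index = 1L,
                  moiety = "peptide", peptide_index = 1L, mass = 100)
  tr <- trajectory(top, list(frame(matrix(c(1, 1, 0.07), 1), c(2, 3, 5))),
                   frame_interval = 1)
  pr <- density_profile(tr, 1L, slice_width = 0.15)
  expect_equal(sum(pr$density > 0), 1)
  expect_equal(max(pr$density), 100 / (2 * 3 * 0.15) * 1.66053906660)
})

test_that("profiles conserve mass and respect slice-width changes", {
  tr <- simulate_brush(synthetic_params(n_chains = 9, n_steps = 1000,
                                        seed = 5))
  for (w in c(0.15, 0.3)) {
    pr <- density_profile(tr, slice_width = w, group_by = "moiety")
    for (g in colnames(pr$density)) {
      integrated <- sum(pr$density[, g]) * pr$slice_width * pr$box_xy_area /
        1.66053906660
      expect_equal(integrated, unname(pr$total_mass[g]), tolerance = 1e-6)
    }
  }
})

test_that("uniform random gas is flat within Poisson bands", {
  set.seed(3)
  n <- 4000
  box <- c(5, 5, 6)
  top <- topology(atom_name = rep("CA", n), residue_name = "ALA",
                  residue_index = seq_len(n), moiety = "peptide",
                  peptide_index = 1L, mass = 10)
  pos <- cbind(runif(n, 0, 5), runif(n, 0, 5), runif(n, 0, 6))
  tr <- trajectory(top, list(frame(pos, box)), frame_interval = 1)
  pr <- density_profile(tr, slice_width = 0.5)
  # interior slices (the last may be partly empty by construction)
  interior <- pr$density[pr$z_centers < 5.5, 1]
  expected_per_slice <- n * 0.5 / 6
  sigma <- sqrt(expected_per_slice)
  counts <- interior * (5 * 5 * 0.5) / 1.66053906660 / 10
  expect_true(all(abs(counts - expected_per_slice) < 4 * sigma))
})

test_that("threshold distance interpolates the outermost crossing", {
  mk_profile <- function(z, d) {
    structure(list(z_centers = z, density = cbind(all = d),
                   slice_width = diff(z)[1], window = c(0, 1),
                   box_xy_area = 1, total_mass = 1),
              class = "sam_density_profile")
  }
  # step profile: 400 below 5 nm, 0 beyond
  z <- seq(0.075, 10, by = 0.15)
  step <- mk_profile(z, ifelse(z < 5, 400, 0))
  d_step <- threshold_distance(step, 200)
  expect_lt(abs(d_step - 5), 0.15)
  # linear ramp 400 at 0 -> 0 at 10 crosses 200 at exactly 5
  ramp <- mk_profile(z, 400 * (1 - z / 10))
  expect_equal(threshold_distance(ramp, 200), 5, tolerance = 1e-6)
  # never reached
  low <- mk_profile(z, rep(100, length(z)))
  expect_warning(res <- threshold_distance(low, 200), "never reaches")
  expect_true(is.na(res))
  # monotone non-decreasing as the threshold drops
  ds <- vapply(c(300, 200, 100, 50), function(th) {
    threshold_distance(ramp, th)
  }, numeric(1))
  expect_true(all(diff(ds) >= 0))
})

test_that("centroid shift is zero for identical and exact for translated", {
  tr <- simulate_brush(synthetic_params(n_chains = 4, n_steps = 500,
                                        seed = 2))
  pep <- select_atoms(tr$topology, moiety = "peptide")
  pr <- density_profile(tr, pep)
  expect_equal(density_centroid_shift(pr, pr), 0)
  # rigid translation by -0.7 nm; the 2.1037 lift keeps atoms off the
  # knife-edge slice boundaries the initial lattice frame sits on
  shifted <- tr
  shifted$frames <- lapply(tr$frames, function(f) {
    f$positions[, 3] <- f$positions[, 3] + 2.1037 - 0.7
    f
  })
  base <- tr
  base$frames <- lapply(tr$frames, function(f) {
    f$positions[, 3] <- f$positions[, 3] + 2.1037
    f
  })
  pr_b <- density_profile(base, pep, slice_width = 0.35)
  pr_a <- density_profile(shifted, pep, slice_width = 0.35)
  expect_equal(density_centroid_shift(pr_b, pr_a), -0.7, tolerance = 1e-9)
  # grid mismatch is an error
  pr_w <- density_profile(base, pep, slice_width = 0.2)
  expect_error(density_centroid_shift(pr_b, pr_w), "grid")
})

test_that("profiles are invariant under rigid XY translation with wrapping", {
  tr <- simulate_brush(synthetic_params(n_chains = 4, n_steps = 400,
                                        seed = 9))
  pep <- select_atoms(tr$topology, moiety = "peptide")
  moved <- tr
  moved$frames <- lapply(tr$frames, function(f) {
    f$positions[, 1] <- (f$positions[, 1] + 1.7) %% f$box[1]
    f$positions[, 2] <- (f$positions[, 2] + 0.9) %% f$box[2]
    f
  })
  expect_equal(density_profile(moved, pep)$density,
               density_profile(tr, pep)$density)
})

test_that("convergence series matches a hand-built distance oracle", {
  # 3 chains at fixed distances from a 1-atom "protein"
  top <- topology(
    atom_name = rep("CB", 4), residue_name = c("TRP", "TRP", "TRP", "GLY"),
    residue_index = 1:4,
    moiety = c("peptide", "peptide", "peptide", "protein"),
    peptide_index = c(1L, 2L, 3L, -1L), element = "C",
    is_sidechain = c(TRUE, TRUE, TRUE, FALSE))
  p1 <- rbind(c(1, 1, 1.3), c(1, 1, 2), c(1, 1, 9), c(1, 1, 1))
  p2 <- rbind(c(1, 1, 1.5), c(1, 1, 1.6), c(1, 1, 9), c(1, 1, 1))
  tr <- toy_trajectory(list(p1, p2), box = c(5, 5, 12), top = top)
  ser <- convergence_min_distance(tr, protein_sel = 4L)
  # chains 1 (0.3 then 0.5) and 2 (1.0 then 0.6) qualify at 0.7; chain 3 never
  expect_equal(ser$mean_min_dist, c(mean(c(0.3, 1.0)), mean(c(0.5, 0.6))))
  # permanently touching peptide gives a constant series
  solo <- toy_trajectory(list(p1[c(1, 4), ], p1[c(1, 4), ] + 0),
                         box = c(5, 5, 12),
                         top = topology(
                           atom_name = c("CB", "CA"),
                           residue_name = c("TRP", "GLY"),
                           residue_index = 1:2,
                           moiety = c("peptide", "protein"),
                           peptide_index = c(1L, -1L), element = "C",
                           is_sidechain = c(TRUE, FALSE)))
  expect_equal(unique(convergence_min_distance(solo)$mean_min_dist), 0.3)
  # no qualifying peptide -> empty series with a warning
  faraway <- toy_trajectory(list(p1[c(3, 4), ]), box = c(5, 5, 12),
                            top = topology(
                              atom_name = c("CB", "CA"),
                              residue_name = c("TRP", "GLY"),
                              residue_index = 1:2,
                              moiety = c("peptide", "protein"),
                              peptide_index = c(1L, -1L), element = "C",
                              is_sidechain = c(TRUE, FALSE)))
  expect_warning(empty <- convergence_min_distance(faraway), "no peptide")
  expect_equal(nrow(empty), 0)
})

test_that("tensile centroid shift grows with the pulling strength", {
  ok <- 0
  for (sd in 1:5) {
    base <- synthetic_params(n_chains = 9, beads_per_chain = 8,
                             linker_beads = 2, n_steps = 5000,
                             save_stride = 250, seed = sd)
    runs <- lapply(c(0, 0.005, 0.01), function(a) {
      p <- base; p$pull_acceleration <- a
      simulate_brush(p)
    })
    pep <- select_atoms(runs[[1]]$topology, moiety = "peptide")
    prof <- lapply(runs, function(tr) {
      density_profile(tr, pep, last_window(tr, 0.005))
    })
    sh <- vapply(2:3, function(k) {
      abs(density_centroid_shift(prof[[1]], prof[[k]]))
    }, numeric(1))
    if (sh[1] > 0 && sh[2] > sh[1]) ok <- ok + 1
  }
  expect_gte(ok, 4)
})
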