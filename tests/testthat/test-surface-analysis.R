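# SASA, patch-to-sphere scale-up, height maps and pocket detection

mk_sphere_system <- function(pos, vdw) {
  n <- nrow(pos)
  top <- topology(atom_name = rep("CA", n), residue_name = "ALA",
                  residue_index = seq_len(n), moiety = "peptide",
                  peptide_index = 1L, element = "C", vdw_radius = vdw)
  list(top = top, frm = frame(pos, c(200, 200, 200)))
}

test_that("an isolated sphere has its closed-form area", {
  s <- mk_sphere_system(matrix(c(100, 100, 100), 1), 0.15)
  res <- sasa(s$frm, s$top, probe_radius = 0.15)
  expect_equal(res$total, 4 * pi * 0.3^2, tolerance = 1e-9)
  expect_equal(unname(res$per_peptide), res$total)
})

test_that("distant atoms are additive; overlapping match the cap formula", {
  far <- mk_sphere_system(rbind(c(40, 40, 40), c(140, 140, 140)), 0.15)
  res <- sasa(far$frm, far$top, probe_radius = 0.15)
  expect_equal(res$total, 2 * 4 * pi * 0.3^2, tolerance = 1e-9)
  set.seed(31)
  for (rep in 1:50) {
    r1 <- runif(1, 0.1, 0.3); r2 <- runif(1, 0.1, 0.3)
    p <- runif(1, 0.1, 1.5)
    R1 <- r1 + p; R2 <- r2 + p
    d <- runif(1, abs(R1 - R2) + 0.01, R1 + R2 - 0.01)
    s <- mk_sphere_system(rbind(c(100, 100, 100), c(100, 100, 100 + d)),
                          c(r1, r2))
    got <- sasa(s$frm, s$top, probe_radius = p, n_points = 960)$per_atom
    want <- two_sphere_sasa(R1, R2, d)
    expect_equal(unname(got), want, tolerance = 2 / sqrt(960) * max(want))
  }
})

test_that("a fully caged atom has zero accessible area", {
  # 12 neighbours at contact (icosahedral-ish cage via fibonacci directions)
  k <- 0:11
  z <- 1 - 2 * (k + 0.5) / 12
  rho <- sqrt(1 - z^2)
  phi <- pi * (3 - sqrt(5)) * k
  cage <- cbind(rho * cos(phi), rho * sin(phi), z) * 0.25
  pos <- rbind(c(0, 0, 0), sweep(cage, 2, c(0, 0, 0), `+`)) +
    matrix(100, 13, 3)
  s <- mk_sphere_system(pos, c(0.15, rep(0.3, 12)))
  res <- sasa(s$frm, s$top, probe_radius = 0.15)
  expect_lt(res$per_atom[1] / (4 * pi * 0.3^2), 0.02)
})

test_that("SASA converges in sphere points and decreases with crowding", {
  set.seed(17)
  pos <- matrix(runif(150, 2, 4), ncol = 3) + 100
  s <- mk_sphere_system(pos, 0.2)
  a1 <- sasa(s$frm, s$top, probe_radius = 0.15, n_points = 960)$total
  a2 <- sasa(s$frm, s$top, probe_radius = 0.15, n_points = 3840)$total
  expect_lt(abs(a1 - a2) / a2, 0.01)
  # adding an occluder can only reduce the area of the original set
  s13 <- mk_sphere_system(rbind(pos, c(103, 103, 103)), 0.2)
  a3 <- sasa(s13$frm, s13$top, probe_radius = 0.15)
  expect_lte(sum(a3$per_atom[seq_len(nrow(pos))]), a1 + 1e-9)
})

test_that("SASA respects the XY periodic boundary", {
  # two atoms touching through the X boundary occlude each other
  n <- 2
  top <- topology(atom_name = rep("CA", n), residue_name = "ALA",
                  residue_index = 1:2, moiety = "peptide",
                  peptide_index = 1L, element = "C", vdw_radius = 0.2)
  frm <- frame(rbind(c(0.05, 2, 2), c(4.95, 2, 2)), c(5, 5, 5))
  wrapped <- sasa(frm, top, probe_radius = 0.15)$total
  apart <- sasa(frame(rbind(c(1, 2, 2), c(4, 2, 2)), c(5, 5, 5)),
                top, probe_radius = 0.15)$total
  expect_lt(wrapped, apart - 1e-6)
})

test_that("patch-to-sphere scale-up reproduces the published arithmetic", {
  val <- scale_patch_to_sphere(63, 10.32 * 9.99, 10)
  expect_lt(abs(val - 780) / 780, 0.03)     # "about 780 nm2"
  expect_gt(val / 75, 10)                   # > ten IgV-domain surfaces
  expect_equal(scale_patch_to_sphere(0, 100, 10), 0)
  expect_equal(scale_patch_to_sphere(126, 10.32 * 9.99, 10), 2 * val)
  expect_error(scale_patch_to_sphere(63, 0, 10))
})

# flat slab of atoms plus an optional carved cylindrical well
slab_system <- function(box = c(12, 12, 10), top_z = 5, well = NULL,
                        spacing = 0.2) {
  g <- expand.grid(x = seq(0.1, box[1] - 0.05, by = spacing),
                   y = seq(0.1, box[2] - 0.05, by = spacing))
  z <- rep(top_z, nrow(g))
  if (!is.null(well)) {
    inside <- sqrt((g$x - well$x)^2 + (g$y - well$y)^2) < well$radius
    z[inside] <- top_z - well$depth
  }
  n <- nrow(g)
  top <- topology(atom_name = rep("CA", n), residue_name = "ALA",
                  residue_index = seq_len(n), moiety = "peptide",
                  peptide_index = 1L, element = "C", vdw_radius = 0.2)
  list(top = top, frm = frame(cbind(g$x, g$y, z), box))
}

test_that("a flat layer has a constant surface and no pockets", {
  s <- slab_system()
  hm <- height_map(s$frm, s$top)
  expect_lt(diff(range(hm$top_surface)), 2 * 0.2)  # within one vdw radius
  expect_equal(nrow(hm$pockets), 0)
  expect_false(accommodates_probe(hm)$accommodates)
})

test_that("a carved 4 x 3 nm well is detected and accommodates the probe", {
  s <- slab_system(top_z = 6, well = list(x = 6, y = 6, radius = 1.5,
                                          depth = 4))
  hm <- height_map(s$frm, s$top, grid_resolution = 0.2)
  expect_equal(nrow(hm$pockets), 1)
  expect_equal(hm$pockets$depth, 4, tolerance = 0.2)
  expect_equal(hm$pockets$width, 3, tolerance = 0.25)
  acc <- accommodates_probe(hm, probe_depth = 4, probe_width = 3)
  expect_true(acc$accommodates)
  expect_equal(nrow(acc$pockets), 1)
  # every pocket depth bounded by the global Z range of the selection
  expect_lte(max(hm$pockets$depth),
             diff(range(s$frm$positions[, 3])) + 2 * 0.2)
})

test_that("shallow wells do not qualify for the probe", {
  s <- slab_system(top_z = 6, well = list(x = 6, y = 6, radius = 1.5,
                                          depth = 2))
  hm <- height_map(s$frm, s$top)
  expect_false(accommodates_probe(hm, 4, 3)$accommodates)
  expect_true(accommodates_probe(hm, 1.8, 3)$accommodates)
})

test_that("height maps shift with XY translation modulo grid registration", {
  s <- slab_system(top_z = 6, well = list(x = 6, y = 6, radius = 1.5,
                                          depth = 4))
  moved <- s$frm
  moved$positions[, 1] <- (moved$positions[, 1] + 2) %% 12  # 10 whole cells
  hm0 <- height_map(s$frm, s$top)
  hm1 <- height_map(moved, s$top)
  expect_equal(sort(hm1$top_surface), sort(hm0$top_surface))
  expect_equal(hm1$pockets$depth, hm0$pockets$depth, tolerance = 1e-9)
  expect_equal(hm1$pockets$width, hm0$pockets$width, tolerance = 1e-9)
})
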