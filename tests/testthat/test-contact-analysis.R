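# Switching-function scores, close contacts, persistence, contact energy

test_that("switch term matches direct arithmetic and its r0 limit", {
  expect_equal(switch_term(0), 1)
  expect_equal(switch_term(0.3), (1 - 0.5^6) / (1 - 0.5^14))
  expect_equal(switch_term(0.6), 6 / 14, tolerance = 1e-12)
  # continuity across the removable singularity
  eps <- 1e-8
  expect_lt(abs(switch_term(0.6 - eps) - 6 / 14), 1e-6)
  expect_lt(abs(switch_term(0.6 + eps) - 6 / 14), 1e-6)
})

test_that("switch term is strictly decreasing and bounded", {
  r <- seq(0, 3, length.out = 1000)
  v <- switch_term(r)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 1))
  # long-range decay: negligible beyond 5 * r0
  expect_lt(switch_term(3), 1e-3)
})

test_that("non-default exponents and r0 are honoured", {
  p <- switch_params(r0 = 1, num_exp = 2, den_exp = 4)
  expect_equal(switch_term(0.5, p), (1 - 0.25) / (1 - 0.0625))
  expect_equal(switch_term(1, p), 0.5)
  expect_error(switch_params(num_exp = 6, den_exp = 6))
})

test_that("cell-list S function matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(20:200, 1)
    box <- c(runif(1, 3, 6), runif(1, 3, 6), 8)
    top <- random_group_topology(n)
    frm <- frame(cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                       runif(n, 0, box[3])), box)
    got <- s_function(frm, top, normalize = FALSE)
    want <- bf_switch_sum(frm$positions, box, top$peptide_index)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("single-pair S values and normalisation are exact", {
  mk <- function(d) {
    top <- topology(atom_name = "CA", residue_name = "ALA",
                    residue_index = 1:2, moiety = "peptide",
                    peptide_index = 1:2, element = "C")
    list(top = top, frm = frame(rbind(c(1, 1, 1), c(1, 1, 1 + d)),
                                c(10, 10, 10)))
  }
  x <- mk(0.6)
  expect_equal(s_function(x$frm, x$top, normalize = FALSE), 6 / 14)
  expect_equal(s_function(x$frm, x$top, normalize = TRUE), 6 / 14)  # n=2
  far <- mk(5)
  expect_lt(s_function(far$frm, far$top, normalize = FALSE), 1e-3)
  one <- topology(atom_name = "CA", residue_name = "ALA", residue_index = 1L,
                  moiety = "peptide", peptide_index = 1L)
  expect_error(s_function(frame(matrix(1, 1, 3), c(5, 5, 5)), one),
               "at least two")
})

test_that("S counts pairs through the XY periodic boundary", {
  top <- topology(atom_name = "CA", residue_name = "ALA", residue_index = 1:2,
                  moiety = "peptide", peptide_index = 1:2, element = "C")
  # 0.05 and 9.95 in a 10-box are 0.1 apart through the boundary
  frm <- frame(rbind(c(0.05, 5, 5), c(9.95, 5, 5)), c(10, 10, 10))
  expect_equal(s_function(frm, top, normalize = FALSE),
               switch_term(0.1), tolerance = 1e-12)
})

test_that("close contacts use a strict cutoff and match brute force", {
  top <- topology(atom_name = "CA", residue_name = "ALA", residue_index = 1:2,
                  moiety = c("peptide", "protein"),
                  peptide_index = c(1L, -1L), element = "C")
  mk_traj <- function(d) {
    trajectory(top, list(frame(rbind(c(1, 1, 1), c(1, 1, 1 + d)),
                               c(10, 10, 10))), frame_interval = 1)
  }
  expect_equal(unname(close_contacts(mk_traj(0.49), 1L, 2L)$counts), 1)
  expect_equal(unname(close_contacts(mk_traj(0.51), 1L, 2L)$counts), 0)
  expect_equal(unname(close_contacts(mk_traj(0.50), 1L, 2L)$counts), 0)
  expect_equal(unname(close_contacts(mk_traj(0), 1L, 2L)$counts), 1)
  expect_error(close_contacts(mk_traj(0.1), 1L, 1L), "disjoint")
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(20:200, 1)
    box <- c(4, 5, 8)
    pos <- cbind(runif(n, 0, 4), runif(n, 0, 5), runif(n, 0, 8))
    ia <- sample(n, n %/% 2)
    ib <- setdiff(seq_len(n), ia)
    topn <- random_group_topology(n)
    tr <- trajectory(topn, list(frame(pos, box)), frame_interval = 1)
    got <- unname(close_contacts(tr, ia, ib, cutoff = 0.7)$counts)
    expect_identical(got, as.numeric(bf_close_count(pos, box, ia, ib, 0.7)))
  }
})

test_that("persistence map counts contact frames, bounded by the window", {
  # one chain of 2 residues + a 2-spot probe; controlled motions
  top <- topology(atom_name = rep("CA", 4),
                  residue_name = c("ALA", "GLY", "PHE19", "ASP26"),
                  residue_index = c(1L, 2L, 3L, 4L),
                  moiety = c("peptide", "peptide", "protein", "protein"),
                  peptide_index = c(1L, 1L, -1L, -1L), element = "C")
  near <- rbind(c(1, 1, 1), c(1, 1, 2), c(1, 1, 1.3), c(3, 3, 3))
  far <- rbind(c(1, 1, 1), c(1, 1, 2), c(1, 1, 5), c(3, 3, 3))
  spots <- data.frame(name = c("PHE19", "ASP26"))
  # contact in every frame -> full window; alternating -> half
  always <- toy_trajectory(list(near, near, near, near), top = top,
                           dt = 1000)  # 1 ns between frames
  pm <- persistence_map(always, spots)
  expect_equal(pm$values["ALA1", "PHE19"], pm$window_length)
  expect_equal(pm$values["ALA1", "ASP26"], 0)
  alternating <- toy_trajectory(list(near, far, near, far), top = top,
                                dt = 1000)
  pm2 <- persistence_map(alternating, spots)
  expect_equal(pm2$values["ALA1", "PHE19"], pm2$window_length / 2)
  expect_true(all(pm2$values <= pm2$window_length))
  # missing spot is an error naming the absentee
  expect_error(persistence_map(always, data.frame(name = c("PHE19", "TYR56"))),
               "TYR56")
})

test_that("active spot set carries the 12 reference residues", {
  as12 <- active_spots()
  expect_equal(nrow(as12), 12)
  expect_true(all(c("PHE19", "ASP26", "ILE54", "TYR56", "GLN66", "ARG113",
                    "MET115", "ALA121", "ASP122", "TYR123", "LYS124",
                    "ARG125") %in% as12$name))
  expect_false(anyDuplicated(as12$index) > 0)
  expect_equal(active_spots(offset = 5)$index - active_spots()$index,
               rep(5L, 12))
})

test_that("contact energy is linear and validates its matrix", {
  em <- matrix(c(-1, -0.5, -0.5, -2), 2, 2,
               dimnames = list(c("TRP", "PHE"), c("TRP", "PHE")))
  none <- data.frame(res_a = character(0), res_b = character(0),
                     count = integer(0))
  expect_equal(contact_energy(none, em), 0)
  one <- data.frame(res_a = "TRP", res_b = "PHE", count = 1L)
  expect_equal(contact_energy(one, em), -0.5)
  some <- data.frame(res_a = c("TRP", "PHE"), res_b = c("PHE", "PHE"),
                     count = c(2L, 3L))
  expect_equal(contact_energy(some, em), 2 * -0.5 + 3 * -2)
  # additivity over disjoint contact sets
  a <- data.frame(res_a = "TRP", res_b = "TRP", count = 4L)
  ab <- rbind(a, some)
  expect_equal(contact_energy(ab, em),
               contact_energy(a, em) + contact_energy(some, em))
  bad <- matrix(c(0, 1, 2, 0), 2, 2,
                dimnames = list(c("TRP", "PHE"), c("TRP", "PHE")))
  expect_error(contact_energy(one, bad), "symmetric")
  expect_error(contact_energy(data.frame(res_a = "GLY", res_b = "TRP",
                                         count = 1L), em), "GLY")
})

test_that("residue-pair contact aggregation feeds the energy score", {
  top <- topology(atom_name = rep("CA", 3),
                  residue_name = c("TRP", "PHE", "PHE"),
                  residue_index = 1:3,
                  moiety = c("peptide", "protein", "protein"),
                  peptide_index = c(1L, -1L, -1L), element = "C")
  pos <- rbind(c(1, 1, 1), c(1, 1, 1.2), c(1, 1, 1.4))
  tr <- trajectory(top, list(frame(pos, c(5, 5, 5))), frame_interval = 1)
  cp <- contact_pairs_by_residue(tr, 1L, c(2L, 3L))
  expect_equal(sum(cp$count), 2)
  expect_true(all(cp$res_a == "TRP" & cp$res_b == "PHE"))
})
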