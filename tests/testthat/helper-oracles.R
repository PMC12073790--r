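# Independent brute-force oracles used to cross-check the cell-list and
# point-sampling kernels.  Everything here is deliberately O(N^2) base R.

# minimum-image displacement in X/Y, open Z
mi_delta <- function(a, b, box) {
  d <- a - b
  d[1] <- d[1] - box[1] * floor(d[1] / box[1] + 0.5)
  d[2] <- d[2] - box[2] * floor(d[2] / box[2] + 0.5)
  d
}

mi_dist <- function(a, b, box) sqrt(sum(mi_delta(a, b, box)^2))

# all-pairs switching-function sum over atoms of different groups
bf_switch_sum <- function(pos, box, group, p = switch_params(),
                          rtrunc = 5 * p$r0) {
  n <- nrow(pos)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (group[i] < 0 || group[j] < 0 || group[i] == group[j]) next
      r <- mi_dist(pos[i, ], pos[j, ], box)
      if (r < rtrunc) total <- total + switch_term(r, p)
    }
  }
  total
}

# all-pairs strict-cutoff cross count
bf_close_count <- function(pos, box, idx_a, idx_b, cutoff) {
  n <- 0
  for (i in idx_a) {
    for (j in idx_b) {
      if (mi_dist(pos[i, ], pos[j, ], box) < cutoff) n <- n + 1
    }
  }
  n
}

# exact accessible area of two intersecting spheres (expanded radii
# R1, R2, centre distance d): 4*pi*R^2 minus the buried spherical cap
two_sphere_sasa <- function(R1, R2, d) {
  area <- function(R, Ro) {
    if (d >= R + Ro) return(4 * pi * R^2)          # disjoint
    if (d <= abs(R - Ro)) {                        # containment
      return(if (R > Ro) 4 * pi * R^2 else 0)
    }
    h <- R - (d^2 + R^2 - Ro^2) / (2 * d)          # buried cap height
    4 * pi * R^2 - 2 * pi * R * h
  }
  c(area(R1, R2), area(R2, R1))
}

# random small frame: n atoms in a box, all one moiety, distinct groups
random_frame <- function(n, box = c(4, 4, 4), n_groups = 5) {
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  frame(pos, box)
}

random_group_topology <- function(n, n_groups = 5) {
  topology(atom_name = "CA",
           residue_name = "ALA",
           residue_index = seq_len(n),
           moiety = "peptide",
           peptide_index = sample.int(n_groups, n, replace = TRUE),
           element = "C", is_calpha = TRUE)
}

# small two-chain trajectory whose frames we control by hand
toy_trajectory <- function(pos_list, box = c(5, 5, 10), dt = 1,
                           top = NULL) {
  if (is.null(top)) {
    n <- nrow(pos_list[[1]])
    top <- topology(atom_name = "CA", residue_name = "ALA",
                    residue_index = seq_len(n), moiety = "peptide",
                    peptide_index = rep(1:2, length.out = n),
                    element = "C", is_calpha = TRUE)
  }
  frames <- lapply(seq_along(pos_list), function(i) {
    frame(pos_list[[i]], box, time = (i - 1) * dt)
  })
  trajectory(top, frames, frame_interval = dt)
}
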