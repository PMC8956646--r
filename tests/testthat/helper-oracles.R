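# Independent brute-force oracles and hand-built fixtures. These stay free
# of the package's internal code paths they are used to check.

# exhaustive 27-image minimum distance
bf_min_image <- function(delta, box) {
  best <- delta
  bd <- sum(delta^2)
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    cand <- delta + c(i, j, k) * box
    if (sum(cand^2) < bd) { best <- cand; bd <- sum(cand^2) }
  }
  best
}

bf_pair_dist <- function(xi, xj, box) {
  d <- xi - xj
  d <- d - box * round(d / box)
  sqrt(d[1]^2 + d[2]^2 + d[3]^2)
}

# O(N^2) double-loop histogram of ref-partner distances
bf_rdf_counts <- function(x, box, ref, partner, mol, bin_width, nbins,
                          exclude_intra = TRUE) {
  counts <- numeric(nbins)
  for (i in ref) {
    for (j in partner) {
      if (i == j) next
      if (exclude_intra && mol[i] == mol[j]) next
      r <- bf_pair_dist(x[i, ], x[j, ], box)
      if (r < bin_width * nbins) {
        counts[floor(r / bin_width) + 1L] <- counts[floor(r / bin_width) + 1L] + 1
      }
    }
  }
  counts
}

# exhaustive nonbonded energy over inter-group pairs (unordered, once each)
bf_nonbonded <- function(x, box, atoms, ga, gb, cutoff) {
  coul <- 0; vdw <- 0
  seen <- character(0)
  for (i in ga) {
    for (j in gb) {
      if (i == j) next
      if (atoms$molecule[i] == atoms$molecule[j]) next
      key <- paste(min(i, j), max(i, j))
      if (key %in% seen) next
      seen <- c(seen, key)
      r <- bf_pair_dist(x[i, ], x[j, ], box)
      if (r > cutoff) next
      coul <- coul + 332.0637 * atoms$charge[i] * atoms$charge[j] / r
      d0 <- sqrt(atoms$lj_epsilon[i] * atoms$lj_epsilon[j])
      r0 <- atoms$lj_rmin_half[i] + atoms$lj_rmin_half[j]
      vdw <- vdw + d0 * ((r0 / r)^12 - 2 * (r0 / r)^6)
    }
  }
  c(coulomb = coul, vdw = vdw)
}

bf_angle <- function(v1, v2) {
  cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosv))) * 180 / pi
}

# exhaustive all-triples hydrogen-bond scan (donor-H...A convention)
bf_detect_hbonds <- function(x, box, topology, r_max, angle_min) {
  hits <- list()
  mol <- topology$atoms$molecule
  for (k in seq_len(nrow(topology$donors))) {
    h <- topology$donors$hydrogen[k]
    dh <- topology$donors$heavy[k]
    for (a in topology$acceptors) {
      if (a == h || a == dh || mol[a] == mol[h]) next
      dvec <- x[a, ] - x[h, ]
      dvec <- dvec - box * round(dvec / box)
      r <- sqrt(dvec[1]^2 + dvec[2]^2 + dvec[3]^2)
      if (r > r_max) next
      vd <- x[dh, ] - x[h, ]
      vd <- vd - box * round(vd / box)
      if (bf_angle(vd, dvec) < angle_min) next
      hits[[length(hits) + 1L]] <- c(dh, h, a)
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 3))
  do.call(rbind, hits)
}

# a rigid three-atom species whose anchors are never collinear; used for
# local-frame (SDF) fixtures
tri_species <- function(name = "TRI") {
  species_topology(name, tibble::tibble(
    label = c("A1", "A2", "A3"), element = c("C", "O", "N"),
    mass = c(12.011, 15.999, 14.007), charge = c(0.1, -0.3, 0.2),
    lj_epsilon = c(0.07, 0.21, 0.2), lj_rmin_half = c(2.0, 1.77, 1.85)),
    bonds = rbind(c(1L, 2L), c(1L, 3L)))
}

point_sp <- function(name = "PNT") {
  species_topology(name, tibble::tibble(
    label = "P1", element = "Ar", mass = 39.948, charge = 0,
    lj_epsilon = 0, lj_rmin_half = 1))
}

# local TRI geometry: A1 origin, A2 on +x, A3 in the xy-plane
tri_local_coords <- function() {
  rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.4, 1.2, 0))
}

# minimal CHARMM-format DCD writer (header + cell block + float frames),
# only used to exercise the binary trajectory reader
write_minimal_dcd <- function(path, coords_list, box) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- length(coords_list)
  natom <- nrow(coords_list[[1]])
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L   # crystal block present
  icntrl[20] <- 24L  # CHARMM version flag
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(84L, con, size = 4)   # title record: 4 + 80
  writeBin(1L, con, size = 4)
  writeChar(formatC("synthetic fixture", width = 80), con, nchars = 80, eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(natom), con, size = 4)
  writeBin(4L, con, size = 4)
  for (f in seq_len(nf)) {
    writeBin(48L, con, size = 4)
    writeBin(c(box[1], 0, box[2], 0, 0, box[3]), con, size = 8)
    writeBin(48L, con, size = 4)
    for (d in 1:3) {
      writeBin(as.integer(natom * 4), con, size = 4)
      writeBin(coords_list[[f]][, d], con, size = 4)
      writeBin(as.integer(natom * 4), con, size = 4)
    }
  }
  invisible(path)
}
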