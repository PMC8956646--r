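#' Non-bonded pair energy: Coulomb + Lennard-Jones 12-6
#'
#' `E_coul = C q_i q_j / r` with `C = 332.0637` kcal A / (mol e^2)
#' (the `e^2 / 4 pi eps0` conversion for charges in elementary charges and
#' distances in Angstrom), and
#' `E_LJ = D0_ij [ (R0_ij / r)^12 - 2 (R0_ij / r)^6 ]` in the R_min
#' convention, whose minimum is exactly `-D0_ij` at `r = R0_ij`.
#' Combining rules follow the CHARMM convention implied by that functional
#' form: well depth geometric (`D0_ij = sqrt(eps_i eps_j)`), minimum
#' distance arithmetic (`R0_ij = rmin_half_i + rmin_half_j`).
#'
#' @param atom_i,atom_j Lists (or single-row data frames) with fields
#'   `charge` (e), `lj_epsilon` (kcal/mol), `lj_rmin_half` (A).
#' @param r Distance (A), > 0; may be a vector.
#' @return Tibble with columns `coulomb`, `lj`, `total` (kcal/mol).
#' @export
#' @examples
#' a <- list(charge = 1, lj_epsilon = 0.2, lj_rmin_half = 1.5)
#' b <- list(charge = -1, lj_epsilon = 0.2, lj_rmin_half = 1.5)
#' pair_energy(a, b, r = 2)   # coulomb = -166.03185 kcal/mol
pair_energy <- function(atom_i, atom_j, r) {
  if (any(r <= 0)) abort("pair distance must be > 0")
  coul <- .COULOMB_K * atom_i$charge * atom_j$charge / r
  d0 <- sqrt(atom_i$lj_epsilon * atom_j$lj_epsilon)
  r0 <- atom_i$lj_rmin_half + atom_j$lj_rmin_half
  s6 <- (r0 / r)^6
  lj <- d0 * (s6^2 - 2 * s6)
  tibble(coulomb = coul, lj = lj, total = coul + lj)
}

# 1-2 and 1-3 bonded exclusion pairs (global, 0-based for the C++ kernels)
exclusion_pairs <- function(topology) {
  b <- topology$bonds
  if (!nrow(b)) return(matrix(integer(0), ncol = 2))
  adj <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
  p12 <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  p13 <- list()
  for (center in names(adj)) {
    nb <- adj[[center]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(sort(nb), 2)
      p13[[center]] <- t(cmb)
    }
  }
  out <- unique(rbind(p12, if (length(p13)) do.call(rbind, p13)))
  out - 1L
}

#' Non-bonded interaction energy between two groups
#'
#' Sums [pair_energy()] over all inter-group atom pairs within a plain
#' (unshifted, unswitched) cutoff under the minimum-image convention,
#' per frame, decomposed into Coulomb and van der Waals terms. By default
#' only intermolecular pairs contribute (the species-pair interaction
#' tables of interest are intermolecular); with
#' `include_intramolecular = TRUE`, 1-2 and 1-3 bonded pairs are still
#' excluded. No mesh-Ewald long-range part is included; the plain-cutoff
#' truncation is recorded in the result metadata.
#'
#' @param traj A `mix_traj`.
#' @param group_a,group_b Selections.
#' @param cutoff Pair cutoff (A), at most `min(box)/2`; 12 A is the
#'   conventional choice.
#' @param include_intramolecular Include non-bonded pairs within one
#'   molecule (minus 1-2/1-3 exclusions).
#' @param frames Optional frame subset.
#' @return Tibble subclass `mix_energy` with per-frame columns `frame`,
#'   `time`, `e_coul`, `e_vdw`, `e_total` (kcal/mol); trajectory means in
#'   kcal/mol and kJ/mol are in the `summary` attribute, and a
#'   per-species-pair mean table in `species_pairs`.
#' @export
nonbonded_energy <- function(traj, group_a, group_b, cutoff = 12,
                             include_intramolecular = FALSE, frames = NULL) {
  stopifnot(inherits(traj, "mix_traj"))
  top <- traj$topology
  ga <- as_selection(top, group_a)
  gb <- as_selection(top, group_b)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (cutoff > min(traj$box[frames, ]) / 2 + 1e-9) {
    abort(sprintf("cutoff %g exceeds min(box)/2 = %g", cutoff,
                  min(traj$box[frames, ]) / 2))
  }
  at <- top$atoms
  excl <- exclusion_pairs(top)
  e <- vapply(frames, function(f) {
    energy_frame_cpp(frame_coords(traj, f), traj$box[f, ], at$charge,
                     at$lj_epsilon, at$lj_rmin_half, at$molecule,
                     ga - 1L, gb - 1L, cutoff, include_intramolecular,
                     excl, .COULOMB_K)
  }, numeric(2))
  out <- tibble(frame = frames, time = traj$times[frames],
                e_coul = unname(e[1, ]), e_vdw = unname(e[2, ]),
                e_total = unname(e[1, ] + e[2, ]))
  # species-pair decomposition (means over frames)
  spec_a <- unique(at$species[ga])
  spec_b <- unique(at$species[gb])
  pairs <- unique(t(apply(expand.grid(spec_a, spec_b,
                                      stringsAsFactors = FALSE), 1, sort)))
  sp_tab <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    sa <- intersect(ga, at$index[at$species == pairs[k, 1]])
    sb <- intersect(gb, at$index[at$species == pairs[k, 2]])
    if (!length(sa) || !length(sb)) return(NULL)
    ek <- vapply(frames, function(f) {
      energy_frame_cpp(frame_coords(traj, f), traj$box[f, ], at$charge,
                       at$lj_epsilon, at$lj_rmin_half, at$molecule,
                       sa - 1L, sb - 1L, cutoff, include_intramolecular,
                       excl, .COULOMB_K)
    }, numeric(2))
    tibble(species_a = pairs[k, 1], species_b = pairs[k, 2],
           e_coul = mean(ek[1, ]), e_vdw = mean(ek[2, ]),
           e_total = mean(ek[1, ] + ek[2, ]))
  })
  structure(out,
            summary = tibble(
              e_coul_kcal = mean(out$e_coul), e_vdw_kcal = mean(out$e_vdw),
              e_total_kcal = mean(out$e_total),
              e_coul_kj = mean(out$e_coul) * .KCAL_TO_KJ,
              e_vdw_kj = mean(out$e_vdw) * .KCAL_TO_KJ,
              e_total_kj = mean(out$e_total) * .KCAL_TO_KJ),
            species_pairs = sp_tab, cutoff = cutoff,
            truncation = "plain cutoff, no shift/switch, no Ewald",
            class = c("mix_energy", class(out)))
}

#' @export
tidy.mix_energy <- function(x, ...) as_tibble(unclass_profile(x))

#' @export
glance.mix_energy <- function(x, ...) attr(x, "summary")

#' @export
autoplot.mix_energy <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("e_coul", "e_vdw", "e_total"),
                            names_to = "term", values_to = "energy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$energy,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "energy (kcal/mol)", colour = NULL)
}
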