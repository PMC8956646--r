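#' Define the topology of one molecular species
#'
#' A species topology carries everything the analyses need to know about one
#' molecule type: atom labels and elements, masses, partial charges,
#' Lennard-Jones parameters in the R_min convention (well depth `lj_epsilon`
#' in kcal/mol and half-minimum distance `lj_rmin_half` in Angstrom), the
#' covalent bond list, and which sites act as hydrogen-bond donors (heavy
#' atom + its hydrogen) or acceptors.
#'
#' @param name Species name, e.g. `"MEN"` or `"CAP"`.
#' @param atoms Data frame with columns `label`, `element`, `mass` (amu),
#'   `charge` (e), `lj_epsilon` (kcal/mol, >= 0), `lj_rmin_half` (Angstrom, > 0).
#' @param bonds Two-column matrix/data frame of atom indices (1-based within
#'   the species) for covalent bonds. May be `NULL` for bond-less species.
#' @param donors Data frame with columns `heavy`, `hydrogen` (atom labels);
#'   each hydrogen must be covalently bonded to its heavy atom.
#' @param acceptors Character vector of acceptor atom labels.
#' @return An object of class `mix_species`.
#' @export
#' @examples
#' water <- species_topology(
#'   "WAT",
#'   atoms = data.frame(
#'     label = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
#'     mass = c(15.999, 1.008, 1.008), charge = c(-0.834, 0.417, 0.417),
#'     lj_epsilon = c(0.1521, 0, 0), lj_rmin_half = c(1.7682, 0.2, 0.2)
#'   ),
#'   bonds = rbind(c(1, 2), c(1, 3)),
#'   donors = data.frame(heavy = c("OW", "OW"), hydrogen = c("HW1", "HW2")),
#'   acceptors = "OW"
#' )
species_topology <- function(name, atoms, bonds = NULL, donors = NULL,
                             acceptors = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  atoms <- as_tibble(atoms)
  req <- c("label", "element", "mass", "charge", "lj_epsilon", "lj_rmin_half")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atoms table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(atoms$label)) {
    abort(sprintf("species '%s': atom labels must be unique", name))
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    abort(sprintf("species '%s': masses must be strictly positive", name))
  }
  if (any(atoms$lj_epsilon < 0)) {
    abort(sprintf("species '%s': lj_epsilon must be >= 0", name))
  }
  if (any(atoms$lj_rmin_half <= 0)) {
    abort(sprintf("species '%s': lj_rmin_half must be > 0", name))
  }
  n <- nrow(atoms)
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    storage.mode(bonds) <- "integer"
    if (ncol(bonds) != 2L) abort("bonds must have two columns")
    if (any(bonds < 1L) || any(bonds > n)) {
      abort(sprintf("species '%s': bond indices out of range", name))
    }
  } else {
    bonds <- matrix(integer(0), ncol = 2L)
  }
  if (!is.null(donors) && nrow(as.data.frame(donors))) {
    donors <- as_tibble(donors)
    stopifnot(all(c("heavy", "hydrogen") %in% names(donors)))
    for (k in seq_len(nrow(donors))) {
      ih <- match(donors$heavy[k], atoms$label)
      id <- match(donors$hydrogen[k], atoms$label)
      if (is.na(ih) || is.na(id)) {
        abort(sprintf("species '%s': donor pair (%s, %s) uses unknown labels",
                      name, donors$heavy[k], donors$hydrogen[k]))
      }
      bonded <- any((bonds[, 1] == ih & bonds[, 2] == id) |
                      (bonds[, 1] == id & bonds[, 2] == ih))
      if (!bonded) {
        abort(sprintf(
          "species '%s': donor hydrogen %s is not bonded to heavy atom %s",
          name, donors$hydrogen[k], donors$heavy[k]))
      }
      n_bonds_h <- sum(bonds == id)
      if (n_bonds_h != 1L) {
        abort(sprintf(
          "species '%s': donor hydrogen %s must appear in exactly one bond",
          name, donors$hydrogen[k]))
      }
    }
  } else {
    donors <- tibble(heavy = character(0), hydrogen = character(0))
  }
  if (length(acceptors) && !all(acceptors %in% atoms$label)) {
    abort(sprintf("species '%s': unknown acceptor label(s)", name))
  }
  structure(
    list(name = name, atoms = atoms, bonds = bonds, donors = donors,
         acceptors = as.character(acceptors)),
    class = "mix_species"
  )
}

#' @export
print.mix_species <- function(x, ...) {
  cat(sprintf("<mix_species> %s: %d atoms, %d bonds, %d donor H, %d acceptors\n",
              x$name, nrow(x$atoms), nrow(x$bonds), nrow(x$donors),
              length(x$acceptors)))
  invisible(x)
}

#' Assemble the full system topology of a mixture
#'
#' Concatenates `counts[i]` copies of each species into a flat atom table.
#' Molecules are contiguous atom runs (species blocks in the given order),
#' matching how mixture boxes are packed. Donor/acceptor sites and bonds are
#' lifted to global atom indices, and the mixture composition (molar
#' percentages) is recorded.
#'
#' @param species List of [species_topology()] objects.
#' @param counts Integer vector of molecule counts, one per species.
#' @return Object of class `mix_topology` with elements `atoms` (tibble:
#'   `index`, `species`, `molecule`, `label`, `element`, `mass`, `charge`,
#'   `lj_epsilon`, `lj_rmin_half`), `bonds` (global index matrix), `donors`
#'   (tibble of global `heavy`/`hydrogen` indices), `acceptors` (global
#'   indices), `species` (the input list) and `composition`.
#' @export
system_topology <- function(species, counts) {
  if (inherits(species, "mix_species")) species <- list(species)
  stopifnot(length(species) == length(counts), all(counts >= 0))
  counts <- as.integer(counts)
  atom_tabs <- list()
  bonds <- list()
  donors <- list()
  acceptors <- integer(0)
  offset <- 0L
  mol <- 0L
  for (s in seq_along(species)) {
    sp <- species[[s]]
    stopifnot(inherits(sp, "mix_species"))
    na <- nrow(sp$atoms)
    don_h <- match(sp$donors$hydrogen, sp$atoms$label)
    don_d <- match(sp$donors$heavy, sp$atoms$label)
    acc <- match(sp$acceptors, sp$atoms$label)
    for (m in seq_len(counts[s])) {
      mol <- mol + 1L
      atom_tabs[[length(atom_tabs) + 1L]] <- mutate(
        sp$atoms,
        index = offset + seq_len(na), species = sp$name, molecule = mol
      )
      if (nrow(sp$bonds)) {
        bonds[[length(bonds) + 1L]] <- sp$bonds + offset
      }
      if (length(don_h)) {
        donors[[length(donors) + 1L]] <-
          tibble(heavy = don_d + offset, hydrogen = don_h + offset)
      }
      if (length(acc)) acceptors <- c(acceptors, acc + offset)
      offset <- offset + na
    }
  }
  atoms <- bind_rows(atom_tabs)
  atoms <- atoms[, c("index", "species", "molecule", "label", "element",
                     "mass", "charge", "lj_epsilon", "lj_rmin_half")]
  total <- sum(counts)
  composition <- tibble(
    species = vapply(species, function(s) s$name, character(1)),
    count = counts,
    molar_percent = if (total > 0) 100 * counts / total else rep(NA_real_, length(counts))
  )
  if (total > 0 && abs(sum(composition$molar_percent) - 100) > 1e-9) {
    abort("internal error: molar percentages do not sum to 100")
  }
  structure(
    list(atoms = atoms,
         bonds = if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), ncol = 2),
         donors = if (length(donors)) bind_rows(donors) else tibble(heavy = integer(0), hydrogen = integer(0)),
         acceptors = acceptors,
         species = species,
         composition = composition),
    class = "mix_topology"
  )
}

#' @export
print.mix_topology <- function(x, ...) {
  cat(sprintf("<mix_topology> %d atoms, %d molecules, %d species\n",
              nrow(x$atoms), max(c(0L, x$atoms$molecule)), nrow(x$composition)))
  print(x$composition)
  invisible(x)
}

n_atoms_topology <- function(topology) nrow(topology$atoms)

#' Select atoms by species and label pattern
#'
#' Selection expressions take the form `"SPECIES"`, `"SPECIES:LABEL"` or
#' `":LABEL"`; `LABEL` may be a comma-separated list and may use shell-style
#' wildcards (e.g. `"CAP:CT*"`). The same expression on the same topology
#' always yields the same ordered index set.
#'
#' @param topology A `mix_topology`.
#' @param expr Selection expression string.
#' @return Integer vector of global atom indices (class `mix_selection`),
#'   carrying the expression as attribute `expr`.
#' @export
#' @examples
#' # select_atoms(top, "MEN:OA")
select_atoms <- function(topology, expr) {
  stopifnot(inherits(topology, "mix_topology"),
            is.character(expr), length(expr) == 1L)
  parts <- strsplit(expr, ":", fixed = TRUE)[[1]]
  sp <- if (length(parts) >= 1L) parts[1] else ""
  lab <- if (length(parts) >= 2L) parts[2] else ""
  keep <- rep(TRUE, nrow(topology$atoms))
  if (nzchar(sp)) keep <- keep & topology$atoms$species == sp
  if (nzchar(lab)) {
    pats <- strsplit(lab, ",", fixed = TRUE)[[1]]
    lab_ok <- Reduce(`|`, lapply(pats, function(p) {
      grepl(utils::glob2rx(p), topology$atoms$label)
    }))
    keep <- keep & lab_ok
  }
  idx <- topology$atoms$index[keep]
  if (!length(idx)) abort(sprintf("selection '%s' matches no atoms", expr))
  structure(idx, expr = expr, class = c("mix_selection", "integer"))
}

as_selection <- function(topology, x) {
  if (inherits(x, "mix_selection")) return(x)
  if (is.character(x)) return(select_atoms(topology, x))
  idx <- as.integer(x)
  if (anyDuplicated(idx)) abort("selection indices must be unique")
  if (any(idx < 1L) || any(idx > nrow(topology$atoms))) {
    abort("selection indices out of range")
  }
  structure(idx, expr = "<indices>", class = c("mix_selection", "integer"))
}

#' Read / write a topology sidecar file
#'
#' The sidecar is a YAML document listing, per species, the atom table
#' (label, element, mass, charge, lj_epsilon, lj_rmin_half), bonds, donor
#' pairs and acceptor labels, plus the molecule counts of the mixture.
#'
#' @param path File path.
#' @return `read_topology()` returns a `mix_topology`;
#'   `write_topology()` returns `path` invisibly.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) abort(sprintf("topology file not found: %s", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species)) abort("topology sidecar lacks a 'species' block")
  species <- lapply(doc$species, function(sp) {
    atoms <- bind_rows(lapply(sp$atoms, as_tibble))
    bonds <- if (length(sp$bonds)) do.call(rbind, lapply(sp$bonds, as.integer)) else NULL
    donors <- if (length(sp$donors)) bind_rows(lapply(sp$donors, as_tibble)) else NULL
    species_topology(sp$name, atoms, bonds = bonds, donors = donors,
                     acceptors = unlist(sp$acceptors) %||% character(0))
  })
  counts <- vapply(doc$species, function(sp) as.integer(sp$count), integer(1))
  system_topology(species, counts)
}

#' @rdname read_topology
#' @param topology A `mix_topology` to serialize.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "mix_topology"))
  doc <- list(species = lapply(seq_along(topology$species), function(s) {
    sp <- topology$species[[s]]
    list(
      name = sp$name,
      count = topology$composition$count[s],
      atoms = lapply(seq_len(nrow(sp$atoms)), function(i) as.list(sp$atoms[i, ])),
      bonds = if (nrow(sp$bonds)) lapply(seq_len(nrow(sp$bonds)), function(i) as.integer(sp$bonds[i, ])) else list(),
      donors = if (nrow(sp$donors)) lapply(seq_len(nrow(sp$donors)), function(i) as.list(sp$donors[i, ])) else list(),
      acceptors = as.list(sp$acceptors)
    )
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
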