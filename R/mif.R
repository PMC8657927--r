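# Molecular interaction fields: probe definitions, grid construction and
# per-point interaction energies (Lennard-Jones + electrostatic +
# hydrogen bond), plus the shape-shell TIP pseudo-field.

#' Per-element force-field parameter table
#'
#' Small editable Lennard-Jones parameter set (rmin in Angstrom, epsilon in
#' kcal/mol) used for probe-atom mixing. Values are generic published-style
#' magnitudes for heavy atoms in organic molecules; unknown elements fall
#' back to the `"*"` row.
#'
#' @return data.frame with columns `element`, `rmin`, `epsilon`.
#' @export
element_parameters <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I", "*"),
    rmin    = c(1.20, 1.90, 1.75, 1.70, 2.10, 2.00, 1.55, 1.95, 2.10, 2.25, 1.90),
    epsilon = c(0.02, 0.12, 0.16, 0.20, 0.20, 0.25, 0.08, 0.28, 0.35, 0.40, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Define an interaction probe
#'
#' @param name probe name (conventionally DRY, O, N1 or TIP).
#' @param lj_epsilon LJ well depth, kcal/mol.
#' @param lj_rmin LJ minimum-energy distance, Angstrom.
#' @param charge probe charge, e.
#' @param hb_role one of `"none"`, `"acceptor"`, `"donor"`; an acceptor
#'   probe pairs with donor-flagged atoms and vice versa.
#' @param energy_cutoff node-filtering cutoff, kcal/mol (negative).
#' @param hb_epsilon,hb_rmin 6-4 hydrogen-bond well depth (kcal/mol) and
#'   optimum heavy-atom distance (Angstrom).
#' @return list of class `probe_spec`.
#' @export
probe_spec <- function(name, lj_epsilon, lj_rmin, charge = 0,
                       hb_role = c("none", "acceptor", "donor"),
                       energy_cutoff = -0.5, hb_epsilon = 4.0, hb_rmin = 2.9) {
  hb_role <- match.arg(hb_role)
  if (energy_cutoff >= 0) stop("energy_cutoff must be negative")
  structure(list(name = name, lj_epsilon = lj_epsilon, lj_rmin = lj_rmin,
                 charge = charge, hb_role = hb_role,
                 energy_cutoff = energy_cutoff, hb_epsilon = hb_epsilon,
                 hb_rmin = hb_rmin),
            class = "probe_spec")
}

#' The four standard GRIND probes
#'
#' DRY (hydrophobic, pure dispersion), O (sp2 carbonyl-oxygen hydrogen-bond
#' acceptor), N1 (amide-nitrogen hydrogen-bond donor) and TIP (molecular
#' shape / steric hot spots). Default node-filtering cutoffs are
#' -0.5, -2.6, -4.2 and -0.75 kcal/mol respectively.
#'
#' @return named list of `probe_spec` objects.
#' @export
default_probes <- function() {
  list(
    DRY = probe_spec("DRY", lj_epsilon = 0.25, lj_rmin = 1.9, charge = 0,
                     hb_role = "none", energy_cutoff = -0.5),
    O   = probe_spec("O", lj_epsilon = 0.20, lj_rmin = 1.7, charge = -0.45,
                     hb_role = "acceptor", energy_cutoff = -2.6),
    N1  = probe_spec("N1", lj_epsilon = 0.16, lj_rmin = 1.75, charge = 0.35,
                     hb_role = "donor", energy_cutoff = -4.2),
    TIP = probe_spec("TIP", lj_epsilon = 0.15, lj_rmin = 1.7, charge = 0,
                     hb_role = "none", energy_cutoff = -0.75)
  )
}

#' Build a regular grid around a molecule
#'
#' Axis-aligned box: the molecular bounding box expanded by `margin` on
#' every side; `dims = ceiling(extent / spacing) + 1` points per axis with
#' the origin at the minimum corner.
#'
#' @param molecule a `molecule3d`.
#' @param spacing grid step, Angstrom (default 0.5).
#' @param margin padding beyond the molecular extent, Angstrom (default 5).
#' @return list of class `grid_spec` with `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(molecule, spacing = 0.5, margin = 5.0) {
  if (spacing <= 0) stop("spacing must be positive")
  lo <- apply(molecule$coords, 2L, min) - margin
  hi <- apply(molecule$coords, 2L, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  structure(list(origin = unname(lo), spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' Cartesian coordinates of all grid points
#'
#' Points are ordered x-fastest (column-major in i, j, k).
#'
#' @param grid a `grid_spec`.
#' @return numeric matrix `prod(dims)` x 3.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(a)
    grid$origin[a] + grid$spacing * (seq_len(grid$dims[a]) - 1L))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  pts
}

# idealized hydrogen-bond directions: unit vector from the mean bonded
# neighbour (or the molecular centroid for bondless atoms) towards the
# atom, i.e. pointing away from the substituents into the interaction
# lobe. Atoms with no usable reference get a zero vector, which the energy
# kernel treats as isotropic via |cos| clamping -- we instead mark them
# isotropic by using the atom->point direction itself (cos = 1): encoded
# here as a zero row handled below.
.hb_directions <- function(mol) {
  n <- n_atoms(mol)
  dir <- matrix(0, n, 3L)
  nb <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  centroid <- colMeans(mol$coords)
  for (i in seq_len(n)) {
    ref <- if (length(nb[[i]]) > 0) {
      colMeans(mol$coords[nb[[i]], , drop = FALSE])
    } else centroid
    v <- mol$coords[i, ] - ref
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) dir[i, ] <- v / nv
  }
  dir
}

.hb_flag_codes <- function(mol) {
  vapply(mol$flags, function(f) {
    if ("hba" %in% f) 1L else if ("hbd" %in% f) 2L else 0L
  }, integer(1))
}

.atom_lj <- function(mol, params = element_parameters()) {
  idx <- match(mol$elements, params$element)
  idx[is.na(idx)] <- match("*", params$element)
  list(rmin = params$rmin[idx], epsilon = params$epsilon[idx])
}

#' Probe interaction energy at arbitrary points
#'
#' Evaluates the three energy components at each point: Lennard-Jones
#' (Lorentz-Berthelot mixing against the per-element parameter table),
#' electrostatics with the distance-dependent dielectric eps(r) = 4r, and
#' a directional 6-4 hydrogen-bond well (weighted by cos^2 of the angle to
#' the atom's idealized interaction direction) between the probe and
#' complementary flagged atoms. A probe-atom pair closer than 0.1 A
#' contributes the flat core clamp of +5 kcal/mol instead of its diverging
#' terms; elsewhere the r^-12 repulsion keeps atomic cores positive.
#'
#' @param molecule a `molecule3d`.
#' @param points numeric matrix (n x 3) of evaluation points, Angstrom.
#' @param probe a `probe_spec`.
#' @param params per-element LJ table (default [element_parameters()]).
#' @return data.frame with columns `E_lj`, `E_el`, `E_hb`, `E` (kcal/mol).
#' @export
probe_energy <- function(molecule, points, probe,
                         params = element_parameters()) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (!all(is.finite(points))) stop("points must be finite")
  lj <- .atom_lj(molecule, params)
  role <- match(probe$hb_role, c("none", "acceptor", "donor")) - 1L
  comp <- mif_energies_cpp(
    points, molecule$coords, molecule$charges, lj$epsilon, lj$rmin,
    .hb_flag_codes(molecule), .hb_directions(molecule),
    probe$lj_epsilon, probe$lj_rmin, probe$charge, role,
    probe$hb_epsilon, probe$hb_rmin, 0.1, 5.0
  )
  data.frame(E_lj = comp[, 1], E_el = comp[, 2], E_hb = comp[, 3],
             E = comp[, 1] + comp[, 2] + comp[, 3])
}

.new_field <- function(grid, probe, comp) {
  structure(
    list(grid = grid, probe = probe,
         E_lj = comp[, 1], E_el = comp[, 2], E_hb = comp[, 3],
         energy = comp[, 1] + comp[, 2] + comp[, 3]),
    class = "probe_field"
  )
}

#' Compute a molecular interaction field
#'
#' Places the probe at every grid point and records the total interaction
#' energy together with its Lennard-Jones, electrostatic and hydrogen-bond
#' components. The TIP probe is special-cased to the shape-shell
#' pseudo-field of [tip_field()].
#'
#' @param molecule a `molecule3d`.
#' @param probe a `probe_spec`.
#' @param grid a `grid_spec` (default built from the molecule with 0.5 A
#'   spacing and 5 A margin).
#' @param params per-element LJ table.
#' @return object of class `probe_field` with per-point `energy` and
#'   components, ordered as [grid_points()].
#' @export
compute_mif <- function(molecule, probe, grid = build_grid(molecule),
                        params = element_parameters()) {
  if (identical(probe$name, "TIP"))
    return(tip_field(molecule, grid, probe = probe, params = params))
  comp <- as.matrix(probe_energy(molecule, grid_points(grid), probe,
                                 params)[, 1:3])
  .new_field(grid, probe, comp)
}

#' @export
print.probe_field <- function(x, ...) {
  cat(sprintf("<probe_field> %s: %d points, E in [%.2f, %.2f] kcal/mol\n",
              x$probe$name, length(x$energy), min(x$energy), max(x$energy)))
  invisible(x)
}

#' Molecular-shape (TIP) pseudo-field
#'
#' The published shape-probe functional form is unavailable, so the shape
#' field is a documented surrogate: the steric LJ field of the probe
#' defines a molecular body (`E_lj >= iso_level`); grid points of the body
#' with at least one of their 6-neighbours outside form the shape shell.
#' Each shell point scores `-1 * convexity`, where convexity is the
#' fraction of its 26-neighbourhood lying outside the body, rescaled to
#' `[0, 1]` over the shell; all other points are 0. Convex protrusions --
#' steric hot spots -- score most negative.
#'
#' @param molecule a `molecule3d`.
#' @param grid a `grid_spec`.
#' @param iso_level body iso-level on the steric LJ field, kcal/mol
#'   (default +0.5).
#' @param probe TIP `probe_spec` (for LJ parameters and the node cutoff).
#' @param params per-element LJ table.
#' @return `probe_field` whose pseudo-energy is stored in the LJ component.
#' @export
tip_field <- function(molecule, grid = build_grid(molecule), iso_level = 0.5,
                      probe = default_probes()$TIP,
                      params = element_parameters()) {
  lj <- .atom_lj(molecule, params)
  comp <- mif_energies_cpp(
    grid_points(grid), molecule$coords, numeric(n_atoms(molecule)),
    lj$epsilon, lj$rmin, integer(n_atoms(molecule)),
    matrix(0, n_atoms(molecule), 3L),
    probe$lj_epsilon, probe$lj_rmin, 0, 0L, 0, 2.9, 0.1, 5.0
  )
  d <- grid$dims
  body <- array(comp[, 1] >= iso_level, dim = d)
  outside <- !body

  shift <- function(arr, dx, dy, dz, fill) {
    out <- array(fill, dim = d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
    okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
    okz <- sz >= 1 & sz <= d[3]
    out[xs[okx], ys[oky], zs[okz]] <- arr[sx[okx], sy[oky], sz[okz]]
    out
  }

  # 6-neighbour exterior contact defines the shell; 26-neighbour exterior
  # fraction defines convexity. Off-grid neighbours count as outside.
  n_out26 <- array(0L, dim = d)
  shell_touch <- array(FALSE, dim = d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb_out <- shift(outside, dx, dy, dz, fill = TRUE)
    n_out26 <- n_out26 + nb_out
    if (abs(dx) + abs(dy) + abs(dz) == 1L)
      shell_touch <- shell_touch | nb_out
  }
  shell <- body & shell_touch
  energy <- numeric(prod(d))
  if (any(shell)) {
    conv <- n_out26[shell] / 26
    rng <- range(conv)
    w <- if (diff(rng) > 0) (conv - rng[1]) / diff(rng) else rep(1, sum(shell))
    energy[as.vector(shell)] <- -1 * w
  }
  .new_field(grid, probe, cbind(energy, 0, 0))
}

#' Export a field as a flat CSV
#'
#' Columns: grid indices `i, j, k` (1-based), Cartesian `x, y, z` and the
#' energy components.
#'
#' @param field a `probe_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  d <- field$grid$dims
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  pts <- grid_points(field$grid)
  out <- cbind(idx, x = pts[, 1], y = pts[, 2], z = pts[, 3],
               E_lj = field$E_lj, E_el = field$E_el, E_hb = field$E_hb,
               E = field$energy)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a field in OpenDX-style grid text
#'
#' Minimal `dx` regular-grid writer (positions, deltas, one scalar per
#' point in z-fastest order) for visualisation in molecular viewers.
#'
#' @param field a `probe_field`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field_dx <- function(field, path) {
  g <- field$grid; d <- g$dims
  e <- array(field$energy, dim = d)
  vals <- as.vector(aperm(e, c(1, 2, 3))[seq_len(d[1]), , , drop = FALSE])
  # dx convention: z varies fastest
  vals <- as.vector(aperm(e, c(3, 2, 1)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.4f 0 0", g$spacing),
    sprintf("delta 0 %.4f 0", g$spacing),
    sprintf("delta 0 0 %.4f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))
  ), con)
  writeLines(apply(matrix(c(vals, rep(NA, (3 - length(vals) %% 3) %% 3)),
                          ncol = 3, byrow = TRUE), 1L,
                   function(r) paste(sprintf("%.6e", r[!is.na(r)]),
                                     collapse = " ")), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
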