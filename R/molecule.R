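# Molecule3D: a minimal 3D structure container -- typed atoms with
# coordinates, partial charges and optional pharmacophoric feature flags.
# One conformer per object; conformer ensembles are plain lists.

.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904
)

.FEATURE_KINDS <- c("hydrophobic", "hba", "hbd")

#' Construct a 3D molecule
#'
#' A `molecule3d` is the structural currency of the package: a set of typed
#' atoms with Cartesian coordinates (Angstrom), partial charges (e) and
#' optional pharmacophoric feature flags. Bonds are optional -- the synthetic
#' pseudo-compounds are bondless geometric atom sets, while imported
#' structures normally carry a bond table.
#'
#' @param compound_id single string identifier.
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param charges numeric vector of partial charges in units of e
#'   (default all zero).
#' @param flags list (one entry per atom) of character vectors, each a subset
#'   of `c("hydrophobic", "hba", "hbd")`; `NULL` means no flags.
#' @param bonds integer matrix with columns `from`, `to`, `order`
#'   (may have zero rows).
#' @return object of class `molecule3d`.
#' @export
molecule3d <- function(compound_id, elements, coords, charges = NULL,
                       flags = NULL, bonds = NULL) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  n <- nrow(coords)
  if (n < 1L) stop("molecule must contain at least one atom")
  if (length(elements) != n) stop("elements/coords length mismatch")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (is.null(charges)) charges <- numeric(n)
  if (length(charges) != n || !all(is.finite(charges)))
    stop("charges must be finite and one per atom")
  if (is.null(flags)) flags <- rep(list(character(0)), n)
  if (length(flags) != n) stop("flags must have one entry per atom")
  flags <- lapply(flags, function(f) {
    f <- as.character(f)
    if (!all(f %in% .FEATURE_KINDS)) stop("unknown feature flag")
    f
  })
  if (is.null(bonds)) {
    bonds <- matrix(integer(0), ncol = 3L,
                    dimnames = list(NULL, c("from", "to", "order")))
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) != 3L) stop("bonds must have columns from, to, order")
    colnames(bonds) <- c("from", "to", "order")
    storage.mode(bonds) <- "integer"
    if (nrow(bonds) > 0 &&
        (min(bonds[, 1:2]) < 1L || max(bonds[, 1:2]) > n))
      stop("bond atom indices out of range")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(compound_id = compound_id, elements = as.character(elements),
         coords = coords, charges = as.numeric(charges), flags = flags,
         bonds = bonds),
    class = "molecule3d"
  )
}

#' @export
print.molecule3d <- function(x, ...) {
  cat(sprintf("<molecule3d> %s: %d atoms, %d bonds, net charge %+0.3f\n",
              x$compound_id, nrow(x$coords), nrow(x$bonds), net_charge(x)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule3d`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$coords)

#' Net charge of a molecule (sum of partial charges)
#' @param mol a `molecule3d`.
#' @return numeric scalar in units of e.
#' @export
net_charge <- function(mol) sum(mol$charges)

#' Molecular weight from standard atomic masses
#'
#' Hydrogens are only counted if present as explicit atoms.
#'
#' @param mol a `molecule3d`.
#' @return molecular weight in Da.
#' @export
molecular_weight <- function(mol) {
  m <- .ATOMIC_MASS[mol$elements]
  m[is.na(m)] <- 12.011  # unknown elements weighed as carbon
  sum(m)
}

#' Apply a rigid motion (rotation + translation) to a molecule
#'
#' Used throughout the test-suite to assert the alignment independence of
#' the correlogram descriptors.
#'
#' @param mol a `molecule3d`.
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric offset in Angstrom.
#' @return the transformed `molecule3d`.
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  mol$coords <- mol$coords %*% t(rotation) +
    matrix(translation, nrow(mol$coords), 3L, byrow = TRUE)
  dimnames(mol$coords) <- list(NULL, c("x", "y", "z"))
  mol
}

#' Random rotation matrix
#'
#' Uniform over SO(3) (QR of a Gaussian matrix, sign-corrected). Driven by
#' the current RNG state.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Canonical connectivity key of a molecule
#'
#' Graph-canonical string used for duplicate detection during curation.
#' Atoms are labelled by element and iteratively refined with sorted
#' neighbour (label, bond-order) multisets (Morgan-style refinement); the
#' key is the sorted multiset of final labels together with the sorted
#' canonical edge list. Bondless molecules fall back to the element
#' composition plus the sorted, rounded pairwise-distance multiset so that
#' geometric duplicates are still caught.
#'
#' @param mol a `molecule3d`.
#' @return single string; identical for identically connected molecules
#'   irrespective of atom numbering.
#' @export
connectivity_key <- function(mol) {
  n <- n_atoms(mol)
  if (nrow(mol$bonds) == 0L) {
    comp <- paste(sort(table(mol$elements)), sort(unique(mol$elements)),
                  sep = "x", collapse = ".")
    if (n > 1L) {
      d <- round(sort(as.vector(stats::dist(mol$coords))), 2)
      return(paste0("geom:", comp, ":", paste(d, collapse = ",")))
    }
    return(paste0("geom:", comp))
  }
  lab <- mol$elements
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]; o <- mol$bonds[k, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  for (iter in seq_len(n)) {
    new_lab <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (is.null(nb)) return(lab[i])
      paste0(lab[i], "(",
             paste(sort(paste0(o = nb[, 2], ":", lab[nb[, 1]])), collapse = ","),
             ")")
    }, character(1))
    # compress to rank codes to keep strings short
    new_lab <- as.character(match(new_lab, sort(unique(new_lab))))
    new_lab <- paste0(mol$elements, new_lab)
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  edges <- apply(mol$bonds, 1L, function(b) {
    e <- sort(c(lab[b[1]], lab[b[2]]))
    paste0(e[1], "-", e[2], ":", b[3])
  })
  paste0("graph:", paste(sort(lab), collapse = "|"), "//",
         paste(sort(edges), collapse = "|"))
}

#' Canonical molecular frame
#'
#' Rigidly moves the molecule into an intrinsic reference frame: centroid
#' at the origin, axes along the principal axes of the coordinate
#' covariance (decreasing variance), axis signs fixed by the projection
#' skewness (falling back to the most extreme projection when the third
#' moment vanishes) and the third axis completed right-handedly. Because
#' the frame is derived from the geometry alone, any rigid motion of the
#' input yields the same canonical coordinates up to floating-point error
#' -- this is what makes grid-derived descriptors alignment-independent.
#' Molecules whose principal variances are (near-)degenerate keep the
#' centred input axes.
#'
#' @param mol a `molecule3d`.
#' @return the molecule in its canonical frame.
#' @export
canonical_frame <- function(mol) {
  n <- n_atoms(mol)
  ctr <- colMeans(mol$coords)
  X <- sweep(mol$coords, 2L, ctr)
  if (n < 3L) {
    mol$coords <- X
    dimnames(mol$coords) <- list(NULL, c("x", "y", "z"))
    return(mol)
  }
  C <- crossprod(X) / n
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values
  if (min(abs(diff(ev))) < 1e-9 * max(ev, 1e-12)) {
    mol$coords <- X  # degenerate inertia: keep input axes
    dimnames(mol$coords) <- list(NULL, c("x", "y", "z"))
    return(mol)
  }
  axes <- eg$vectors  # columns, decreasing eigenvalue
  for (k in 1:2) {
    p <- X %*% axes[, k]
    s <- sum(p^3)
    if (abs(s) < 1e-9) s <- p[which.max(abs(p))]
    if (s < 0) axes[, k] <- -axes[, k]
  }
  axes[, 3] <- c(axes[2, 1] * axes[3, 2] - axes[3, 1] * axes[2, 2],
                 axes[3, 1] * axes[1, 2] - axes[1, 1] * axes[3, 2],
                 axes[1, 1] * axes[2, 2] - axes[2, 1] * axes[1, 2])
  mol$coords <- X %*% axes
  dimnames(mol$coords) <- list(NULL, c("x", "y", "z"))
  mol
}
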