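# SDF V2000 structure I/O via ChemmineR. Partial charges and feature
# flags travel as SDF data fields (`PARTIAL_CHARGES`, `FEATURE_FLAGS`),
# one comma-separated value per atom, so a single file carries everything
# a molecule3d holds.

.flags_to_string <- function(flags)
  paste(vapply(flags, function(f) paste(f, collapse = "|"), character(1)),
        collapse = ",")

.string_to_flags <- function(s, n) {
  if (is.na(s) || !nzchar(s)) return(rep(list(character(0)), n))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(parts) < n)  # strsplit drops trailing empty fields
    parts <- c(parts, rep("", n - length(parts)))
  if (length(parts) != n) stop("FEATURE_FLAGS length does not match atoms")
  lapply(parts, function(p)
    if (nzchar(p)) strsplit(p, "|", fixed = TRUE)[[1]] else character(0))
}

.mol_to_chemmine_sdf <- function(mol) {
  n <- n_atoms(mol)
  ab <- cbind(mol$coords, matrix(0L, n, 13L))
  rownames(ab) <- paste(mol$elements, seq_len(n), sep = "_")
  colnames(ab) <- paste0("C", 1:16)
  if (nrow(mol$bonds) > 0) {
    bb <- cbind(mol$bonds[, 1:3, drop = FALSE], matrix(0L, nrow(mol$bonds), 4L))
  } else {
    bb <- matrix(integer(0), ncol = 7L)
  }
  colnames(bb) <- paste0("C", 1:7)
  rownames(bb) <- if (nrow(bb)) as.character(seq_len(nrow(bb))) else NULL
  header <- c(
    Molecule_Name = mol$compound_id, Source = "grindqsar", Comment = "",
    Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                          n, nrow(bb))
  )
  db <- c(PARTIAL_CHARGES = paste(sprintf("%.6f", mol$charges), collapse = ","),
          FEATURE_FLAGS = .flags_to_string(mol$flags))
  methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
               header = header, atomblock = ab, bondblock = bb,
               datablock = db)
}

#' Write molecules to an SDF V2000 file
#'
#' Coordinates go in the atom block; partial charges and pharmacophoric
#' feature flags are stored as SDF data fields and recovered by
#' [read_molecules_sdf()].
#'
#' @param molecules list of `molecule3d` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_molecules_sdf <- function(molecules, path) {
  sdfs <- lapply(molecules, .mol_to_chemmine_sdf)
  ids <- vapply(molecules, function(m) m$compound_id, character(1))
  names(sdfs) <- ids
  sdfset <- methods::new(
    methods::getClass("SDFset", where = asNamespace("ChemmineR")),
    SDF = sdfs, ID = ids)
  # bondless pseudo-compounds produce an empty bond block, which the
  # writer formats with a harmless recycling warning
  withCallingHandlers(
    ChemmineR::write.SDF(sdfset, path),
    warning = function(w) {
      if (grepl("multiple of vector length", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

#' Read molecules from an SDF V2000 file
#'
#' @param path SDF file path.
#' @return list of `molecule3d` objects, named by compound id.
#' @export
read_molecules_sdf <- function(path) {
  # bond-free records trip ChemmineR's validity heuristic; they are fine
  sdfset <- withCallingHandlers(
    ChemmineR::read.SDFset(path),
    warning = function(w) {
      if (grepl("invalid SDFs detected", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- lapply(seq_along(ChemmineR::sdfid(sdfset)), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    n <- nrow(ab)
    elements <- gsub("_.*", "", rownames(ab))
    coords <- ab[, 1:3, drop = FALSE]
    db <- ChemmineR::datablock(sdf)
    charges <- if ("PARTIAL_CHARGES" %in% names(db)) {
      as.numeric(strsplit(db[["PARTIAL_CHARGES"]], ",", fixed = TRUE)[[1]])
    } else numeric(n)
    flags <- if ("FEATURE_FLAGS" %in% names(db)) {
      .string_to_flags(db[["FEATURE_FLAGS"]], n)
    } else NULL
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3)
      bb[, 1:3, drop = FALSE] else NULL
    molecule3d(ChemmineR::sdfid(sdfset)[i], elements, coords,
               charges = charges, flags = flags, bonds = bonds)
  })
  names(out) <- vapply(out, function(m) m$compound_id, character(1))
  out
}
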