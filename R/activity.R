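# Activity-table handling: molar pIC50, lipophilic efficiency, activity
# classes and CSV I/O. An "activity table" is a plain data.frame with one
# row per compound.

#' Molar pIC50 from a micromolar IC50
#'
#' pIC50 is the negative decadic logarithm of the half-maximal inhibitory
#' concentration expressed in mol/L; inputs are in the micromolar units
#' activity tables are normally reported in.
#'
#' @param ic50_um IC50 in micromolar; positive, finite (vectorised).
#' @return numeric vector of pIC50 values (molar scale).
#' @examples
#' compute_pic50(1)     # 6
#' compute_pic50(6.60)  # 5.18, Araguspongine C
#' @export
compute_pic50 <- function(ic50_um) {
  if (!is.numeric(ic50_um) || any(!is.finite(ic50_um)) || any(ic50_um <= 0))
    stop("ic50_um must be positive and finite")
  -log10(ic50_um * 1e-6)
}

#' Lipophilic efficiency
#'
#' LipE = pIC50 - clogP, the standard activity/lipophilicity balance used
#' for template prioritisation.
#'
#' @param pic50 molar pIC50 (vectorised).
#' @param clogp calculated logP (vectorised).
#' @return numeric vector of LipE values.
#' @export
compute_lipe <- function(pic50, clogp) {
  if (any(!is.finite(pic50)) || any(!is.finite(clogp)))
    stop("pic50 and clogp must be finite")
  pic50 - clogp
}

#' Build an activity table from raw columns
#'
#' Derives molar `pic50`, `lipe` and the boolean `is_active` class from the
#' raw IC50/clogP columns. The default activity threshold of 160 uM splits
#' the dataset at the gap between the most and least active compounds.
#'
#' @param compound_id character vector of compound identifiers (unique).
#' @param class_label scaffold class per compound (e.g. "A", "B", "C", "M").
#' @param ic50_um IC50 in micromolar.
#' @param clogp calculated logP (input column; never computed here).
#' @param active_threshold_um activity threshold in micromolar (default 160).
#' @return data.frame with columns `compound_id`, `class`, `ic50_um`,
#'   `clogp`, `pic50`, `lipe`, `is_active`.
#' @export
activity_table <- function(compound_id, class_label, ic50_um, clogp,
                           active_threshold_um = 160) {
  stopifnot(length(compound_id) == length(ic50_um),
            length(clogp) == length(ic50_um))
  if (anyDuplicated(compound_id)) stop("compound_id must be unique")
  pic50 <- compute_pic50(ic50_um)
  data.frame(
    compound_id = as.character(compound_id),
    class = as.character(class_label),
    ic50_um = as.numeric(ic50_um),
    clogp = as.numeric(clogp),
    pic50 = pic50,
    lipe = compute_lipe(pic50, clogp),
    is_active = ic50_um <= active_threshold_um,
    stringsAsFactors = FALSE
  )
}

#' Read an activity CSV
#'
#' Expected columns: `compound_id`, `class`, `ic50_um`, `clogp`. Derived
#' columns are recomputed on read so a table written by
#' [write_activity_csv()] round-trips exactly.
#'
#' @param path CSV file path.
#' @param active_threshold_um activity threshold in micromolar.
#' @return activity table data.frame (see [activity_table()]).
#' @export
read_activity_csv <- function(path, active_threshold_um = 160) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "class", "ic50_um", "clogp")
  if (!all(need %in% names(raw)))
    stop("activity CSV must contain columns: ", paste(need, collapse = ", "))
  activity_table(raw$compound_id, raw$class, raw$ic50_um, raw$clogp,
                 active_threshold_um = active_threshold_um)
}

#' Write an activity CSV
#'
#' Numeric columns are serialised with 17 significant digits so that a
#' write/read cycle reproduces the table bit-exactly.
#'
#' @param records activity table data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(records, path) {
  out <- records
  for (cl in c("ic50_um", "clogp", "pic50", "lipe"))
    if (cl %in% names(out)) out[[cl]] <- sprintf("%.17g", out[[cl]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select a pharmacophore template compound
#'
#' Template selection follows the oral-drug optimum: restrict to compounds
#' with clogP inside `clogp_range`, then take the one with maximal LipE.
#' If no in-range compound reaches `lipe_min` the best in-range compound is
#' still returned and the relaxation is flagged (the canonical template
#' ryanodine has LipE 4.6, below the 5.0 guideline). Ties are broken by
#' lower IC50, then lexicographic id.
#'
#' @param records activity table with `clogp`, `lipe`, `ic50_um`.
#' @param clogp_range numeric length-2 inclusive clogP window (default 2-3).
#' @param lipe_min LipE guideline threshold (default 5.0).
#' @return list with `compound_id`, `lipe`, `clogp`, and logical `relaxed`
#'   (TRUE when the LipE guideline had to be waived).
#' @export
select_template <- function(records, clogp_range = c(2, 3), lipe_min = 5) {
  if (nrow(records) == 0L) stop("empty activity table")
  in_range <- records$clogp >= clogp_range[1] & records$clogp <= clogp_range[2]
  if (!any(in_range))
    stop("no compound with clogP in [", clogp_range[1], ", ",
         clogp_range[2], "]")
  cand <- records[in_range, , drop = FALSE]
  relaxed <- !any(cand$lipe >= lipe_min)
  if (!relaxed) cand <- cand[cand$lipe >= lipe_min, , drop = FALSE]
  ord <- order(-cand$lipe, cand$ic50_um, cand$compound_id)
  best <- cand[ord[1L], ]
  list(compound_id = best$compound_id, lipe = best$lipe,
       clogp = best$clogp, relaxed = relaxed)
}
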