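# Dataset curation: fragment (low-MW) and duplicate removal, with a
# per-reason report. Idempotent by construction.

#' Curate an activity table and its structures
#'
#' Applies the standard library-preparation filters: entries whose
#' molecular weight is below `mw_min` (fragments) are removed, and
#' duplicates -- identified by the canonical connectivity key of the
#' structure (see [connectivity_key()]) -- are collapsed to their first
#' occurrence. Records without a structure are reported but kept.
#'
#' @param records activity table data.frame (see [activity_table()]).
#' @param molecules list of `molecule3d` objects keyed by `compound_id`.
#' @param mw_min fragment threshold in Da (default 200).
#' @return list with `records`, `molecules` (curated, same order retained)
#'   and `report`: counts `fragment`, `duplicate`, `missing_structure` plus
#'   the removed ids per reason.
#' @export
curate <- function(records, molecules, mw_min = 200) {
  mol_ids <- vapply(molecules, function(m) m$compound_id, character(1))
  names(molecules) <- mol_ids
  missing <- setdiff(records$compound_id, mol_ids)

  keep <- rep(TRUE, nrow(records))
  frag_ids <- character(0); dup_ids <- character(0)
  seen_keys <- character(0)
  for (i in seq_len(nrow(records))) {
    id <- records$compound_id[i]
    if (!id %in% mol_ids) next  # no structure: reported, not fatal
    mol <- molecules[[id]]
    if (molecular_weight(mol) < mw_min) {
      keep[i] <- FALSE
      frag_ids <- c(frag_ids, id)
      next
    }
    key <- connectivity_key(mol)
    if (key %in% seen_keys) {
      keep[i] <- FALSE
      dup_ids <- c(dup_ids, id)
    } else {
      seen_keys <- c(seen_keys, key)
    }
  }
  kept_ids <- records$compound_id[keep]
  list(
    records = records[keep, , drop = FALSE],
    molecules = molecules[intersect(names(molecules), kept_ids)],
    report = list(
      fragment = length(frag_ids),
      duplicate = length(dup_ids),
      missing_structure = length(missing),
      removed_fragment_ids = frag_ids,
      removed_duplicate_ids = dup_ids,
      missing_structure_ids = missing
    )
  )
}
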