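# Distance-geometry pharmacophore models: feature perception on 3D
# structures, assignment matching under a global distance tolerance, and
# dataset screening with confusion-matrix output.

#' Construct a pharmacophore model
#'
#' A model is an ordered feature list (kind + radius) plus the symmetric
#' matrix of pairwise feature distances and a single global distance
#' tolerance. The triangle inequality is checked on construction within
#' the tolerance; violations only warn, since published distance tables
#' are rounded.
#'
#' @param features data.frame with columns `feature_id`, `kind` (one of
#'   `"hydrophobic"`, `"hba"`, `"hbd"`) and `radius` (Angstrom, > 0).
#' @param distances symmetric numeric matrix (Angstrom, zero diagonal).
#' @param tolerance global pairwise-distance tolerance, Angstrom
#'   (default 1.5).
#' @param name optional model name.
#' @return object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(features, distances, tolerance = 1.5,
                                name = NULL) {
  stopifnot(all(c("feature_id", "kind", "radius") %in% names(features)))
  if (!all(features$kind %in% .FEATURE_KINDS)) stop("unknown feature kind")
  if (any(features$radius <= 0)) stop("feature radii must be positive")
  m <- nrow(features)
  distances <- as.matrix(distances)
  if (!all(dim(distances) == m)) stop("distance matrix dimension mismatch")
  if (max(abs(distances - t(distances))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(diag(distances) != 0)) stop("distance matrix diagonal must be 0")
  for (i in seq_len(m)) for (j in seq_len(m)) for (k in seq_len(m)) {
    if (distances[i, j] > distances[i, k] + distances[k, j] + tolerance)
      warning(sprintf("triangle inequality violated beyond tolerance (%d,%d,%d)",
                      i, j, k))
  }
  structure(list(features = features, distances = distances,
                 tolerance = tolerance, name = name,
                 exclusion_volumes = NULL),  # reserved, not matched in v1
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat(sprintf("<pharmacophore_model> %s: %d features, tolerance %.2f A\n",
              if (is.null(x$name)) "(unnamed)" else x$name,
              nrow(x$features), x$tolerance))
  invisible(x)
}

.model_feature_row <- function(ids, kinds, radii)
  data.frame(feature_id = ids, kind = kinds, radius = radii,
             stringsAsFactors = FALSE)

.dist_from_lower <- function(m, lower) {
  d <- matrix(0, m, m)
  d[lower.tri(d)] <- lower
  d + t(d)
}

#' The ten built-in distance-geometry pharmacophore models
#'
#' Five-to-four-feature hypotheses (hydrophobic centre, hydrogen-bond
#' acceptors and donors) with their pairwise distance matrices; model 1
#' (Hyd, HBA1 2.62 A, HBA2 4.79 A, HBD1 5.56 A, HBD2 7.68 A from the
#' hydrophobic centre) is the selected final model. All models share the
#' 1.5 A global tolerance; per-feature radii are retained for reporting.
#'
#' @return named list of 10 `pharmacophore_model` objects
#'   (`model1` .. `model10`).
#' @export
builtin_models <- function() {
  hyd <- "hydrophobic"
  mk <- function(n, ids, kinds, radii, lower)
    pharmacophore_model(.model_feature_row(ids, kinds, radii),
                        .dist_from_lower(length(ids), lower), 1.5,
                        name = paste0("model", n))
  list(
    model1 = mk(1, c("Hyd", "HBA1", "HBA2", "HBD1", "HBD2"),
                c(hyd, "hba", "hba", "hbd", "hbd"),
                c(0.75, 1.0, 0.5, 0.75, 0.75),
                c(2.62, 4.79, 5.56, 7.68, 2.61, 3.64, 5.58, 4.57, 3.11, 6.97)),
    model2 = mk(2, c("Hyd", "HBA1", "HBD1", "HBD2", "HBD3"),
                c(hyd, "hba", "hbd", "hbd", "hbd"),
                c(0.75, 1.0, 0.75, 0.75, 0.75),
                c(2.48, 3.46, 5.56, 7.43, 4.17, 3.63, 5.58, 6.33, 7.8, 7.01)),
    model3 = mk(3, c("Hyd", "HBA", "HBD1", "HBD2", "HBD3"),
                c(hyd, "hba", "hbd", "hbd", "hbd"),
                c(0.75, 1.0, 0.75, 0.75, 0.75),
                c(3.95, 3.97, 7.09, 7.29, 3.87, 4.13, 3.41, 2.86, 7.01, 2.62)),
    model4 = mk(4, c("Hyd1", "HBA", "HBD1", "HBD2", "Hyd2"),
                c(hyd, "hba", "hbd", "hbd", hyd),
                c(0.75, 1.0, 0.75, 0.75, 0.75),
                c(2.32, 3.19, 7.69, 6.22, 1.62, 6.91, 4.41, 4.57, 3.17, 2.04)),
    model5 = mk(5, c("Hyd", "HBA", "HBD1", "HBD2", "HBD3"),
                c(hyd, "hba", "hbd", "hbd", "hbd"),
                c(0.75, 1.0, 0.75, 0.75, 0.75),
                c(2.32, 4.56, 2.92, 7.06, 3.01, 1.05, 5.09, 3.61, 7.53, 5.28)),
    model6 = mk(6, c("Hyd", "HBA1", "HBA2", "HBD1", "HBD2"),
                c(hyd, "hba", "hba", "hbd", "hbd"),
                c(0.75, 1.0, 0.5, 0.75, 0.75),
                c(4.32, 4.46, 6.87, 4.42, 2.21, 3.07, 6.05, 5.73, 5.04, 9.61)),
    model7 = mk(7, c("Hyd", "HBA", "HBD1", "HBD2", "HBD3"),
                c(hyd, "hba", "hbd", "hbd", "hbd"),
                c(0.75, 1.0, 0.75, 0.75, 0.75),
                c(2.49, 4.06, 5.08, 6.1, 2.07, 2.8, 6.48, 2.38, 8.87, 6.56)),
    model8 = mk(8, c("Hyd", "HBA1", "HBA2", "HBD"),
                c(hyd, "hba", "hba", "hbd"),
                c(0.75, 1.0, 0.5, 0.75),
                c(4.28, 4.26, 7.08, 2.8, 6.94, 5.42)),
    model9 = mk(9, c("HBA1", "HBA2", "HBA3", "HBD1", "HBD2"),
                c("hba", "hba", "hba", "hbd", "hbd"),
                c(1.0, 1.0, 1.0, 0.75, 0.75),
                c(2.52, 2.05, 4.65, 6.9, 2.07, 2.28, 7.96, 4.06, 5.75, 8.96)),
    model10 = mk(10, c("HBA1", "HBA2", "HBD1", "HBD2"),
                 c("hba", "hba", "hbd", "hbd"),
                 c(1.0, 0.5, 0.75, 0.75),
                 c(3.26, 3.65, 6.96, 6.06, 6.09, 6.33))
  )
}

#' Perceive pharmacophoric features of a molecule
#'
#' Pre-labelled feature flags take precedence: every flagged atom becomes
#' a feature point verbatim. Otherwise features are perceived from
#' elements and bonds: HBD = O/N bearing an explicit H; HBA = carbonyl or
#' ether O (hydroxyls act as donors) and N with an open valence;
#' hydrophobic = the centroid of each ring system and of each aliphatic
#' cluster of >= 2 carbons with no attached heteroatom.
#'
#' @param molecule a `molecule3d`.
#' @return data.frame with `kind`, `x`, `y`, `z`, `anchor` (atom indices,
#'   comma-separated).
#' @export
perceive_features <- function(molecule) {
  flagged <- which(vapply(molecule$flags, length, integer(1)) > 0)
  if (length(flagged) > 0) {
    rows <- do.call(rbind, lapply(flagged, function(i) {
      data.frame(kind = molecule$flags[[i]],
                 x = molecule$coords[i, 1], y = molecule$coords[i, 2],
                 z = molecule$coords[i, 3], anchor = as.character(i),
                 stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    return(rows)
  }
  if (nrow(molecule$bonds) == 0L)
    stop("molecule has neither feature flags nor bonds")

  el <- molecule$elements
  n <- n_atoms(molecule)
  g <- igraph::graph_from_edgelist(molecule$bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  nbrs <- lapply(seq_len(n), function(i)
    as.integer(igraph::neighbors(g, i)))
  order_of <- function(i, j) {
    hit <- (molecule$bonds[, 1] == i & molecule$bonds[, 2] == j) |
      (molecule$bonds[, 1] == j & molecule$bonds[, 2] == i)
    max(molecule$bonds[hit, 3])
  }
  feats <- list()
  add <- function(kind, xyz, anchor)
    feats[[length(feats) + 1L]] <<- data.frame(
      kind = kind, x = xyz[1], y = xyz[2], z = xyz[3],
      anchor = paste(anchor, collapse = ","), stringsAsFactors = FALSE)

  valence <- c(N = 3L, O = 2L)
  for (i in seq_len(n)) {
    if (!el[i] %in% c("N", "O")) next
    nb <- nbrs[[i]]
    has_h <- any(el[nb] == "H")
    bond_sum <- if (length(nb)) sum(vapply(nb, function(j) order_of(i, j),
                                           numeric(1))) else 0
    if (has_h) add("hbd", molecule$coords[i, ], i)
    if (el[i] == "O" && !has_h) {
      # carbonyl (double bond) or ether oxygen; hydroxyls act as donors
      add("hba", molecule$coords[i, ], i)
    } else if (el[i] == "N" && length(nb) < 4L && bond_sum <= valence[["N"]]) {
      # sp2/sp3 nitrogen with an available lone pair
      add("hba", molecule$coords[i, ], i)
    }
  }
  # ring systems: connected components of the subgraph of cycle edges
  bridges <- igraph::bridges(g)
  cyc <- igraph::delete_edges(g, bridges)
  comp <- igraph::components(cyc)
  for (cid in seq_len(comp$no)) {
    mem <- which(comp$membership == cid)
    mem <- mem[igraph::degree(cyc, mem) > 0]
    if (length(mem) >= 3L)
      add("hydrophobic", colMeans(molecule$coords[mem, , drop = FALSE]), mem)
  }
  # aliphatic clusters: >= 2 bonded carbons, none touching a heteroatom
  in_ring <- igraph::degree(cyc) > 0
  plain_c <- which(el == "C" & !in_ring &
                   vapply(nbrs, function(nb) all(el[nb] %in% c("C", "H")),
                          logical(1)))
  if (length(plain_c) >= 2L) {
    sub <- igraph::induced_subgraph(g, plain_c)
    cc <- igraph::components(sub)
    for (cid in seq_len(cc$no)) {
      mem <- plain_c[cc$membership == cid]
      if (length(mem) >= 2L)
        add("hydrophobic", colMeans(molecule$coords[mem, , drop = FALSE]),
            mem)
    }
  }
  if (length(feats) == 0L)
    return(data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), anchor = character(0)))
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  out
}

#' Match a conformer's features against a pharmacophore model
#'
#' Backtracking search over kind-compatible assignments of model features
#' to molecule feature points with pairwise pruning: a partial assignment
#' is extended only while every implied inter-feature distance deviates
#' from the model distance by at most the tolerance. The first admissible
#' complete assignment (deterministic feature order) is returned with
#' `fit_score = 1 - RMS(deviations) / tolerance`; no match scores 0.
#'
#' @param features feature data.frame (from [perceive_features()]).
#' @param model a `pharmacophore_model` (at most 8 features).
#' @return list of class `match_result`: `matched`, `assignment` (molecule
#'   feature row per model feature, or NULL), `fit_score`,
#'   `max_deviation` (Angstrom).
#' @export
match_pharmacophore <- function(features, model) {
  m <- nrow(model$features)
  if (m > 8L) stop("models with > 8 features are not supported")
  tol <- model$tolerance
  no_match <- structure(list(matched = FALSE, assignment = NULL,
                             fit_score = 0, max_deviation = NA_real_),
                        class = "match_result")
  if (nrow(features) == 0L) return(no_match)
  fxyz <- as.matrix(features[, c("x", "y", "z")])
  cand <- lapply(seq_len(m), function(i)
    which(features$kind == model$features$kind[i]))
  if (any(vapply(cand, length, integer(1)) == 0L)) return(no_match)
  fdist <- as.matrix(stats::dist(fxyz))

  assign_vec <- integer(m)
  found <- NULL
  recurse <- function(i) {
    if (!is.null(found)) return()
    if (i > m) { found <<- assign_vec; return() }
    for (a in cand[[i]]) {
      if (a %in% assign_vec[seq_len(i - 1L)]) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (abs(fdist[a, assign_vec[j]] - model$distances[i, j]) > tol) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        assign_vec[i] <<- a
        recurse(i + 1L)
        if (!is.null(found)) return()
        assign_vec[i] <<- 0L
      }
    }
  }
  recurse(1L)
  if (is.null(found)) return(no_match)
  devs <- abs(fdist[found, found] - model$distances)[upper.tri(diag(m))]
  if (m < 2L) devs <- 0
  structure(list(matched = TRUE, assignment = found,
                 fit_score = 1 - sqrt(mean(devs^2)) / tol,
                 max_deviation = max(devs)),
            class = "match_result")
}

#' Screen a dataset against a pharmacophore model
#'
#' A compound is a hit when any of its conformers matches
#' (first-match-stop semantics). Hits are crossed with the activity labels
#' into confusion counts and classification metrics.
#'
#' @param conformer_sets list per compound: either a single `molecule3d`
#'   or a list of conformers.
#' @param is_active logical vector, one label per compound.
#' @param model a `pharmacophore_model`.
#' @return list with `hits` (logical), `best_score` (per compound),
#'   `counts` (`confusion_counts`) and `metrics`
#'   (see [confusion_metrics()]).
#' @export
screen_pharmacophore <- function(conformer_sets, is_active, model) {
  if (length(conformer_sets) == 0L) stop("empty dataset")
  if (length(is_active) != length(conformer_sets))
    stop("one activity label per compound required")
  hits <- logical(length(conformer_sets))
  best <- numeric(length(conformer_sets))
  for (ci in seq_along(conformer_sets)) {
    confs <- conformer_sets[[ci]]
    if (inherits(confs, "molecule3d")) confs <- list(confs)
    if (length(confs) == 0L) stop("compound ", ci, " has no conformer")
    for (conf in confs) {
      res <- match_pharmacophore(perceive_features(conf), model)
      if (res$matched) {
        hits[ci] <- TRUE
        best[ci] <- res$fit_score
        break  # stop after first matching conformation
      }
    }
  }
  counts <- confusion_counts(tp = sum(hits & is_active),
                             tn = sum(!hits & !is_active),
                             fp = sum(hits & !is_active),
                             fn = sum(!hits & is_active))
  list(hits = hits, best_score = best, counts = counts,
       metrics = confusion_metrics(counts))
}

#' Write / read a pharmacophore model as JSON
#'
#' @param model a `pharmacophore_model`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `pharmacophore_model` (reader).
#' @export
write_pharmacophore_json <- function(model, path) {
  jsonlite::write_json(
    list(name = model$name,
         features = model$features,
         distances = model$distances,
         tolerance = model$tolerance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pharmacophore_json
#' @export
read_pharmacophore_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pharmacophore_model(as.data.frame(obj$features),
                      matrix(unlist(obj$distances), nrow(obj$features)),
                      obj$tolerance, name = obj$name)
}
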