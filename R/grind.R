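# Grid-independent descriptors: node filtering (energy cutoff + greedy
# energy/spread selection) and auto/cross correlogram encoding of
# node-node energy products.

.PROBE_PAIRS <- c("DRY-DRY", "O-O", "N1-N1", "TIP-TIP", "DRY-O", "DRY-N1",
                  "DRY-TIP", "O-N1", "O-TIP", "N1-TIP")

#' Discretize a field into nodes
#'
#' Keeps grid points at or below the probe's energy cutoff, then selects up
#' to `max_nodes` of them greedily: the first node is the global energy
#' minimum and each subsequent node maximises
#' `(1 - w) |E|/|E|max + w d_min/d_max`, where `d_min` is the distance to
#' the nearest already-selected node and `d_max` the candidate
#' bounding-box diagonal. The spread term keeps the node set from
#' collapsing into the deepest well.
#'
#' @param field a `probe_field`.
#' @param max_nodes maximum nodes retained (default 100).
#' @param spread_weight weight `w` of the spatial-spread term in `[0, 1]`
#'   (default 0.5).
#' @return data.frame of class `node_set`: `probe`, `x`, `y`, `z`,
#'   `energy`, ordered by selection. Zero rows when nothing passes the
#'   cutoff.
#' @export
filter_nodes <- function(field, max_nodes = 100, spread_weight = 0.5) {
  cutoff <- field$probe$energy_cutoff
  pass <- which(field$energy <= cutoff)
  empty <- data.frame(probe = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), energy = numeric(0))
  class(empty) <- c("node_set", "data.frame")
  if (length(pass) == 0L) return(empty)
  pts <- grid_points(field$grid)[pass, , drop = FALSE]
  en <- field$energy[pass]
  dmax <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  sel <- select_nodes_cpp(pts, en, as.integer(max_nodes), spread_weight,
                          dmax)
  out <- data.frame(probe = field$probe$name, x = pts[sel, 1],
                    y = pts[sel, 2], z = pts[sel, 3], energy = en[sel],
                    stringsAsFactors = FALSE)
  class(out) <- c("node_set", "data.frame")
  out
}

.bin_count <- function(bin_width, max_distance) {
  nb <- as.integer(floor(max_distance / bin_width + 1e-9))
  if (nb < 1L) stop("max_distance must cover at least one bin")
  nb
}

.pair_values <- function(nodes_a, nodes_b, auto, bin_width, n_bins) {
  # all qualifying node pairs: distances, energy products and indices
  if (nrow(nodes_a) == 0L || nrow(nodes_b) == 0L ||
      (auto && nrow(nodes_a) < 2L))
    return(NULL)
  ca <- as.matrix(nodes_a[, c("x", "y", "z")])
  cb <- as.matrix(nodes_b[, c("x", "y", "z")])
  if (auto) {
    idx <- which(upper.tri(matrix(0, nrow(ca), nrow(ca))), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_len(nrow(ca)),
                                 col = seq_len(nrow(cb))))
  }
  dvec <- sqrt(rowSums((ca[idx[, 1], , drop = FALSE] -
                        cb[idx[, 2], , drop = FALSE])^2))
  bin <- as.integer(floor(dvec / bin_width))  # bin b covers [b*w, (b+1)*w)
  ok <- bin >= 0L & bin < n_bins
  if (!any(ok)) return(NULL)
  data.frame(i = idx[ok, 1], j = idx[ok, 2], bin = bin[ok],
             dist = dvec[ok],
             product = nodes_a$energy[idx[ok, 1]] * nodes_b$energy[idx[ok, 2]])
}

#' Maximum auto/cross correlogram (MACC2) encoding
#'
#' For each of the 10 probe pairs and each half-open distance bin
#' `[b*w, (b+1)*w)`, the descriptor value is the maximum node-node energy
#' product over qualifying pairs (two favourable, negative energies give a
#' positive product). Self-pairs are excluded in auto blocks; empty bins
#' are 0.
#'
#' @param nodes_by_probe named list of `node_set`s, one per probe
#'   (names DRY, O, N1, TIP).
#' @param bin_width distance bin width, Angstrom (default 0.4).
#' @param max_distance largest encoded distance, Angstrom (default 24).
#' @return object of class `correlogram`: numeric `values` (named
#'   `pair|bin`), `bin_width`, `max_distance`, and `provenance` (per
#'   nonzero variable the contributing node pair and its distance).
#' @export
encode_macc <- function(nodes_by_probe, bin_width = 0.4, max_distance = 24) {
  if (bin_width <= 0) stop("bin_width must be positive")
  n_bins <- .bin_count(bin_width, max_distance)
  probes <- c("DRY", "O", "N1", "TIP")
  vals <- numeric(0)
  prov <- list()
  for (pair in .PROBE_PAIRS) {
    pq <- strsplit(pair, "-", fixed = TRUE)[[1]]
    auto <- pq[1] == pq[2]
    na_ <- nodes_by_probe[[pq[1]]]
    nb_ <- nodes_by_probe[[pq[2]]]
    if (is.null(na_)) na_ <- data.frame(x = numeric(0), y = numeric(0),
                                        z = numeric(0), energy = numeric(0))
    if (is.null(nb_)) nb_ <- na_[0, ]
    block <- setNames(numeric(n_bins),
                      paste0(pair, "|", seq_len(n_bins) - 1L))
    pairs <- .pair_values(na_, nb_, auto, bin_width, n_bins)
    if (!is.null(pairs)) {
      for (b in unique(pairs$bin)) {
        sub <- pairs[pairs$bin == b, , drop = FALSE]
        best <- sub[which.max(sub$product), ]
        block[b + 1L] <- best$product
        prov[[paste0(pair, "|", b)]] <-
          list(i = best$i, j = best$j, dist = best$dist)
      }
    }
    vals <- c(vals, block)
  }
  structure(list(values = vals, bin_width = bin_width,
                 max_distance = max_distance, provenance = prov),
            class = "correlogram")
}

#' Consistently-selected correlogram (CLACC-style) encoding
#'
#' Starts from the MACC2 vectors of all compounds, then, variable by
#' variable, re-chooses each compound's contributing node pair among the
#' pairs within 90 percent of that compound's bin maximum so as to minimise
#' the variable's coefficient of variation across compounds (at most
#' `max_sweeps` sweeps or until no choice changes). A compound's value can
#' therefore only stay at or drop below its MACC2 value.
#'
#' @param node_sets list (one per compound) of named lists of `node_set`s.
#' @param bin_width,max_distance as in [encode_macc()].
#' @param max_sweeps sweep limit (default 10).
#' @return list of `correlogram` objects, one per compound.
#' @export
encode_clacc <- function(node_sets, bin_width = 0.4, max_distance = 24,
                         max_sweeps = 10) {
  if (length(node_sets) < 2L) stop("CLACC needs at least 2 compounds")
  n_bins <- .bin_count(bin_width, max_distance)
  base <- lapply(node_sets, encode_macc, bin_width = bin_width,
                 max_distance = max_distance)
  # per compound and variable, the candidate products within 90% of max
  cand <- lapply(node_sets, function(ns) {
    out <- list()
    for (pair in .PROBE_PAIRS) {
      pq <- strsplit(pair, "-", fixed = TRUE)[[1]]
      if (is.null(ns[[pq[1]]]) || is.null(ns[[pq[2]]])) next
      pairs <- .pair_values(ns[[pq[1]]], ns[[pq[2]]],
                            pq[1] == pq[2], bin_width, n_bins)
      if (is.null(pairs)) next
      for (b in unique(pairs$bin)) {
        sub <- pairs[pairs$bin == b, , drop = FALSE]
        mx <- max(sub$product)
        out[[paste0(pair, "|", b)]] <- sub$product[sub$product >= 0.9 * mx]
      }
    }
    out
  })
  vars <- names(base[[1]]$values)
  cur <- vapply(base, function(cg) cg$values, numeric(length(vars)))
  cur <- matrix(cur, nrow = length(vars),
                dimnames = list(vars, names(node_sets)))
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (v in vars) {
      present <- which(cur[v, ] != 0)
      if (length(present) < 2L) next
      for (ci in present) {
        opts <- cand[[ci]][[v]]
        if (is.null(opts) || length(opts) < 2L) next
        others <- cur[v, present[present != ci]]
        cv_of <- function(x) {
          m <- mean(c(others, x))
          if (m == 0) Inf else sd(c(others, x)) / abs(m)
        }
        best <- opts[which.min(vapply(opts, cv_of, numeric(1)))]
        if (abs(best - cur[v, ci]) > 1e-12) {
          cur[v, ci] <- best
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- base
  for (ci in seq_along(out)) out[[ci]]$values <- cur[, ci]
  out
}

#' Assemble a descriptor matrix from correlograms
#'
#' @param descriptors list of `correlogram` objects (identical binning),
#'   optionally named by compound id.
#' @param drop_zero drop all-zero columns (default TRUE); the dropped-mask
#'   is recorded so matrices remain comparable.
#' @return list with `X` (compounds x variables), `labels` (human-readable
#'   variable labels such as `"DRY-N1 [7.6-8.0 A]"`), `kept` (logical mask
#'   over the full variable set) and `bin_width`.
#' @export
descriptor_matrix <- function(descriptors, drop_zero = TRUE) {
  bw <- unique(vapply(descriptors, function(d) d$bin_width, numeric(1)))
  md <- unique(vapply(descriptors, function(d) d$max_distance, numeric(1)))
  if (length(bw) != 1L || length(md) != 1L)
    stop("descriptors mix bin_width / max_distance settings")
  X <- t(vapply(descriptors, function(d) d$values,
                numeric(length(descriptors[[1]]$values))))
  if (!is.null(names(descriptors))) rownames(X) <- names(descriptors)
  full <- colnames(X)
  kept <- rep(TRUE, ncol(X))
  if (drop_zero) kept <- colSums(X != 0) > 0
  labels <- variable_labels(full, bw)
  list(X = X[, kept, drop = FALSE], labels = labels[kept], kept = kept,
       all_labels = labels, bin_width = bw, max_distance = md)
}

#' Human-readable labels for correlogram variables
#'
#' @param ids internal ids of the form `"pair|bin"`.
#' @param bin_width bin width in Angstrom.
#' @return character vector like `"DRY-N1 [7.6-8.0 A]"`.
#' @export
variable_labels <- function(ids, bin_width) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  vapply(parts, function(p) {
    b <- as.integer(p[2])
    sprintf("%s [%.1f-%.1f A]", p[1], b * bin_width, (b + 1) * bin_width)
  }, character(1))
}

#' Full MIF-to-descriptor pipeline for a set of molecules
#'
#' Builds a grid per molecule (in the molecule's own frame -- descriptors
#' are alignment-independent), computes the four probe fields, filters
#' nodes and encodes correlograms.
#'
#' @param molecules list of `molecule3d` objects.
#' @param probes probe list (default [default_probes()]).
#' @param spacing,margin grid geometry, Angstrom.
#' @param max_nodes,spread_weight node filtering (see [filter_nodes()]).
#' @param bin_width,max_distance correlogram binning.
#' @param encoder `"macc2"` (default) or `"clacc"`.
#' @param use_canonical_frame move each molecule into its canonical
#'   principal-axes frame before building the grid (default TRUE). This is
#'   what makes the descriptors invariant under rigid motion of the input:
#'   the grid is rebuilt in the molecule's own frame.
#' @return as [descriptor_matrix()], plus `nodes` (per compound).
#' @export
grind_descriptors <- function(molecules, probes = default_probes(),
                              spacing = 0.5, margin = 5.0, max_nodes = 100,
                              spread_weight = 0.5, bin_width = 0.4,
                              max_distance = 24,
                              encoder = c("macc2", "clacc"),
                              use_canonical_frame = TRUE) {
  encoder <- match.arg(encoder)
  if (use_canonical_frame) molecules <- lapply(molecules, canonical_frame)
  node_sets <- lapply(molecules, function(mol) {
    grid <- build_grid(mol, spacing = spacing, margin = margin)
    setNames(lapply(probes, function(pr)
      filter_nodes(compute_mif(mol, pr, grid), max_nodes = max_nodes,
                   spread_weight = spread_weight)),
      vapply(probes, function(pr) pr$name, character(1)))
  })
  names(node_sets) <- vapply(molecules, function(m) m$compound_id,
                             character(1))
  cgs <- if (encoder == "macc2") {
    lapply(node_sets, encode_macc, bin_width = bin_width,
           max_distance = max_distance)
  } else {
    encode_clacc(node_sets, bin_width = bin_width,
                 max_distance = max_distance)
  }
  names(cgs) <- names(node_sets)
  out <- descriptor_matrix(cgs)
  out$nodes <- node_sets
  out$correlograms <- cgs
  out
}
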