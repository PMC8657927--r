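# Synthetic pseudo-compound generator. Produces geometric atom sets with
# typed charges and pharmacophoric feature flags whose statistical
# structure mirrors the curated antagonist dataset the pipeline is built
# for: ~40 compounds in 4 scaffold classes, IC50 spanning 0.0029-20000 uM
# with a 160 uM activity threshold, and activities that are a known sparse
# linear function of the compound's own correlogram variables plus
# Gaussian noise. Pseudo-compounds are not chemically valid molecules --
# every downstream operator consumes geometry, types and charges only.

# 3D embedding of the final pharmacophore model's distance matrix
# (Hyd, HBA1, HBA2, HBD1, HBD2; pairwise distances reproduced to 0.004 A).
.MOTIF_XYZ <- matrix(c(
  -3.046877,  2.155547, -0.074281,
  -1.157010,  0.393152,  0.333204,
   1.353741,  0.291961, -0.372343,
  -1.567796, -3.203815, -0.027092,
   4.417942,  0.363156,  0.140512
), ncol = 3, byrow = TRUE)

.TYPED_CHARGE <- c(C = 0.0, O = -0.40, N = 0.25, P = 0.50)

#' Default sparse ground-truth coefficient map
#'
#' Six informative correlogram variables mirroring the interaction
#' hot-spot story the pipeline is designed to expose: a hydrophobic pair
#' at 6.4-6.8 A, a hydrophobic/donor-probe pair at 7.6-8.0 A, a
#' hydrophobic/shape pair at 5.6-6.0 A and a long donor-contour pair at
#' 10.4-10.8 A raise potency, while a short donor-contour pair (2.4-2.8 A)
#' and an acceptor-contour pair at 9.2-9.6 A lower it. Coefficients are on
#' the scale of the MACC2 energy products the default generator produces
#' (calibrated once against the default geometry and then frozen).
#'
#' @return data.frame with `variable` (internal `pair|bin` id) and `beta`.
#' @export
default_true_beta <- function() {
  data.frame(
    variable = c("DRY-DRY|16", "DRY-N1|19", "DRY-TIP|14",
                 "O-O|26", "O-O|6", "N1-N1|23"),
    beta = c(1.5, 0.25, 1.2, 0.11, -0.06, -0.08),
    stringsAsFactors = FALSE
  )
}

#' Generator configuration
#'
#' Captures the study conditions emulated by the generator. Class weights
#' follow the 12/6/3/19 scaffold-class composition of a 40-compound
#' antagonist panel; IC50 range, activity threshold and the assay-noise SD
#' are the emulated dataset's values.
#'
#' @param n_compounds number of pseudo-compounds (default 40, >= 5).
#' @param class_weights named proportions over classes A/B/C/M.
#' @param ic50_range micromolar IC50 span (default 0.0029-20000).
#' @param active_threshold activity threshold, uM (default 160).
#' @param noise_sd Gaussian noise on pIC50 (default 0.3).
#' @param motif_fraction fraction of compounds carrying the 5-feature
#'   active motif (default 0.5).
#' @param jitter_sd coordinate jitter on planted feature atoms, Angstrom
#'   (default 0.03, keeping planted distances within 0.2 A of the model).
#' @param true_beta sparse coefficient map (see [default_true_beta()]).
#' @param intercept baseline noiseless pIC50 (default 3.1).
#' @param spacing,margin,bin_width,max_distance,max_nodes pipeline
#'   settings used when computing the ground-truth descriptors.
#' @param seed master seed; split into independent geometry / charge /
#'   noise substreams.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 40,
                             class_weights = c(A = 12, B = 6, C = 3, M = 19) / 40,
                             ic50_range = c(0.0029, 20000),
                             active_threshold = 160,
                             noise_sd = 0.3,
                             motif_fraction = 0.5,
                             jitter_sd = 0.03,
                             true_beta = default_true_beta(),
                             intercept = 2.6,
                             spacing = 0.5, margin = 5.0,
                             bin_width = 0.4, max_distance = 24,
                             max_nodes = 100,
                             seed = 1) {
  if (n_compounds < 5L) stop("n_compounds must be >= 5")
  if (abs(sum(class_weights) - 1) > 1e-8) stop("class_weights must sum to 1")
  if (any(ic50_range <= 0) || diff(ic50_range) <= 0)
    stop("ic50_range must be positive and ordered")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(as.list(environment()), class = "generator_config")
}

# independent substream seeds derived from the master seed
.substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 3L),
           c("geometry", "charges", "noise"))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.ring_coords <- function(center, radius, n, normal = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  u <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- u - sum(u * normal) * normal; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ang <- 2 * pi * (seq_len(n) - 1) / n
  t(vapply(ang, function(a) center + radius * (cos(a) * e1 + sin(a) * e2),
           numeric(3)))
}

# one pseudo-compound: returns list(elements, coords, flags, motif info)
.build_compound <- function(class_label, has_motif, jitter_sd) {
  elements <- character(0)
  coords <- matrix(numeric(0), 0, 3)
  flags <- list()
  push <- function(el, xyz, fl = character(0)) {
    elements <<- c(elements, el)
    coords <<- rbind(coords, matrix(xyz, ncol = 3))
    flags <<- c(flags, rep(list(fl), length(el)))
  }
  motif_distances <- NULL
  if (has_motif) {
    xyz <- .MOTIF_XYZ + matrix(rnorm(15, sd = jitter_sd), 5, 3)
    push("C", xyz[1, ], "hydrophobic")
    push("O", xyz[2, ], "hba")
    push("O", xyz[3, ], "hba")
    push("N", xyz[4, ], "hbd")
    push("N", xyz[5, ], "hbd")
    motif_distances <- as.vector(stats::dist(xyz))
    # hydrophobic bulk around the motif's hydrophobic centre, plus a
    # second hydrophobic centre ~6.6 A away (favourable DRY-DRY pair)
    push(rep("C", 6), .ring_coords(xyz[1, ], 1.4, 6))
    second <- xyz[1, ] + c(0, -4.6, 4.7)
    second <- xyz[1, ] + 6.6 * (second - xyz[1, ]) / sqrt(sum((second - xyz[1, ])^2))
    push("C", second, "hydrophobic")
    push(rep("C", 4), .ring_coords(second, 1.35, 4))
  } else {
    # "inactive" arrangement: a long acceptor-acceptor axis and a short
    # donor-donor pair next to a small hydrophobic patch
    base <- c(0, 0, 0)
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    push("O", base + 0.3 * axis, "hba")
    push("O", base + 9.8 * axis, "hba")
    mid <- base + 4.9 * axis + c(0, 2.2, 0)
    push("N", mid, "hbd")
    push("N", mid + c(2.62, 0, 0), "hbd")
    push("C", base + c(-2.5, -2.0, 0.5), "hydrophobic")
    push(rep("C", 5), .ring_coords(base + c(-2.5, -2.0, 0.5), 1.4, 5))
  }
  # class-specific decoration (scaffold flavour, no informative geometry)
  deco_centre <- colMeans(coords) + c(0, 3.5, -3.0)
  if (class_label == "A") {
    push(rep("P", 3), .ring_coords(deco_centre, 2.4, 3))
    push(rep("O", 3), .ring_coords(deco_centre, 3.3, 3, normal = c(0, 1, 0)))
  } else if (class_label == "B") {
    push(rep("C", 10), .ring_coords(deco_centre, 3.6, 10))
  } else if (class_label == "C") {
    push(rep("C", 6), .ring_coords(deco_centre, 1.4, 6))
    push(rep("P", 2), .ring_coords(deco_centre + c(0, 0, 3.0), 2.0, 2))
  } else {
    n_deco <- 4L + sample.int(4, 1)
    push(rep("C", n_deco),
         sweep(matrix(rnorm(3 * n_deco, sd = 2.2), ncol = 3), 2L,
               deco_centre, "+"))
  }
  # pad with inert carbons to land in the 15-60 atom window
  n_pad <- max(0L, 15L - length(elements)) + sample.int(6, 1) - 1L
  if (n_pad > 0)
    push(rep("C", n_pad),
         sweep(matrix(rnorm(3 * n_pad, sd = 2.5), ncol = 3), 2L,
               colMeans(coords), "+"))
  list(elements = elements, coords = coords, flags = flags,
       motif_distances = motif_distances)
}

#' Generate synthetic pseudo-compounds
#'
#' Each compound is a 3D point set of 15-60 atoms with labelled
#' hydrophobic centres, carbonyl-like acceptor oxygens and N-H-like donor
#' nitrogens. Compounds carrying the active motif contain the five-feature
#' arrangement of the final pharmacophore model (acceptors 2.62/4.79 A and
#' donors 5.56/7.68 A from a hydrophobic centre) to within the configured
#' jitter; the rest carry an unfavourable arrangement (short donor-donor
#' and long acceptor-acceptor pairs). Partial charges are assigned by atom
#' type. Deterministic per seed; geometry, charges and downstream noise
#' use independent substreams.
#'
#' @param config a [generator_config()].
#' @return list with `molecules` (list of `molecule3d`) and `truth`
#'   (class, motif flag, planted feature distances, substream seeds,
#'   `true_beta`).
#' @export
generate_molecules <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- .substream_seeds(config$seed)
  classes <- names(config$class_weights)
  built <- .with_seed(seeds[["geometry"]], {
    cls <- sample(classes, config$n_compounds, replace = TRUE,
                  prob = config$class_weights)
    motif <- runif(config$n_compounds) < config$motif_fraction
    lapply(seq_len(config$n_compounds), function(i)
      c(.build_compound(cls[i], motif[i], config$jitter_sd),
        list(class = cls[i], motif = motif[i])))
  })
  charges <- .with_seed(seeds[["charges"]], {
    lapply(built, function(b)
      .TYPED_CHARGE[b$elements] + rnorm(length(b$elements), sd = 0.02))
  })
  ids <- sprintf("SYN%03d", seq_along(built))
  molecules <- lapply(seq_along(built), function(i)
    molecule3d(ids[i], built[[i]]$elements, built[[i]]$coords,
               charges = unname(charges[[i]]), flags = built[[i]]$flags))
  names(molecules) <- ids
  truth <- structure(list(
    compound_id = ids,
    class = vapply(built, `[[`, character(1), "class"),
    motif = vapply(built, `[[`, logical(1), "motif"),
    motif_distances = lapply(built, `[[`, "motif_distances"),
    true_beta = config$true_beta,
    intercept = config$intercept,
    seeds = seeds
  ), class = "syndata_truth")
  list(molecules = molecules, truth = truth)
}

#' Generate activities from the ground-truth linear model
#'
#' The noiseless pIC50 of each compound is `intercept + sum(beta * x)`
#' over its own correlogram variables (computed with the mif/grind
#' pipeline at the configured settings); the observed pIC50 adds
#' `N(0, noise_sd)` assay noise (independent substream) and is censored to
#' the configured IC50 dynamic range. IC50 is back-transformed to uM and
#' the activity class set by the threshold. clogP is drawn per scaffold
#' class in the range typical for that class.
#'
#' @param molecules molecules from [generate_molecules()].
#' @param truth matching `syndata_truth`.
#' @param config the same [generator_config()].
#' @param descriptors optional precomputed [grind_descriptors()] output
#'   for `molecules` (computed here when NULL).
#' @return list with `records` (activity table), `truth` (augmented with
#'   `noiseless_pic50`) and `descriptors`.
#' @export
generate_activities <- function(molecules, truth, config,
                                descriptors = NULL) {
  stopifnot(inherits(truth, "syndata_truth"))
  ids <- vapply(molecules, function(m) m$compound_id, character(1))
  if (!identical(unname(ids), truth$compound_id))
    stop("molecules do not match the supplied truth object")
  if (is.null(descriptors))
    descriptors <- grind_descriptors(
      molecules, spacing = config$spacing, margin = config$margin,
      max_nodes = config$max_nodes, bin_width = config$bin_width,
      max_distance = config$max_distance)
  full <- t(vapply(descriptors$correlograms, function(cg) cg$values,
                   numeric(length(descriptors$correlograms[[1]]$values))))
  tb <- truth$true_beta
  missing_vars <- setdiff(tb$variable, colnames(full))
  if (length(missing_vars) > 0)
    stop("true_beta names unknown variables: ",
         paste(missing_vars, collapse = ", "))
  pic50_lim <- rev(-log10(config$ic50_range * 1e-6))
  # linear predictor, censored to the assay dynamic range (IC50 outside
  # the configured span would not be reportable)
  noiseless <- pmin(pmax(
    truth$intercept +
      as.numeric(full[, tb$variable, drop = FALSE] %*% tb$beta),
    pic50_lim[1]), pic50_lim[2])
  noise <- .with_seed(truth$seeds[["noise"]],
                      rnorm(length(noiseless), sd = config$noise_sd))
  observed <- pmin(pmax(noiseless + noise, pic50_lim[1]), pic50_lim[2])
  ic50 <- 10^(6 - observed)
  clogp <- .with_seed(truth$seeds[["charges"]] + 1L, {
    vapply(truth$class, function(cl) switch(cl,
      A = runif(1, -8.5, -4.0), B = runif(1, 4.5, 8.2),
      C = runif(1, -8.0, -4.0), runif(1, -1.0, 5.0)), numeric(1))
  })
  records <- activity_table(truth$compound_id, truth$class, ic50, clogp,
                            active_threshold_um = config$active_threshold)
  truth$noiseless_pic50 <- noiseless
  list(records = records, truth = truth, descriptors = descriptors)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: molecules, ground-truth descriptors and
#' activities for a configuration.
#'
#' @param config a [generator_config()].
#' @return list with `molecules`, `records`, `truth`, `descriptors`.
#' @export
simulate_qsar_dataset <- function(config = generator_config()) {
  gen <- generate_molecules(config)
  act <- generate_activities(gen$molecules, gen$truth, config)
  list(molecules = gen$molecules, records = act$records,
       truth = act$truth, descriptors = act$descriptors)
}

#' Save a synthetic dataset to disk
#'
#' Writes the SDF structures, the activity CSV and the ground truth as a
#' JSON sidecar.
#'
#' @param dataset output of [simulate_qsar_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_molecules_sdf(dataset$molecules, file.path(dir, "molecules.sdf"))
  write_activity_csv(dataset$records, file.path(dir, "activities.csv"))
  tr <- dataset$truth
  jsonlite::write_json(
    list(compound_id = tr$compound_id, class = tr$class, motif = tr$motif,
         true_beta = tr$true_beta, intercept = tr$intercept,
         noiseless_pic50 = tr$noiseless_pic50),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
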