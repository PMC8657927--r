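# Distance-geometry pharmacophore models, feature perception, matching
# and dataset screening.

test_that("the built-in models carry the published distance geometry", {
  models <- suppressWarnings(builtin_models())
  # one printed distance table (model 3) genuinely breaks the triangle
  # inequality beyond tolerance and must warn on load
  expect_warning(  # both symmetric halves of the (3,5) entry warn
    expect_warning(builtin_models(), "triangle inequality"),
    "triangle inequality")
  expect_length(models, 10)
  m1 <- models$model1
  expect_equal(m1$features$kind,
               c("hydrophobic", "hba", "hba", "hbd", "hbd"))
  expect_equal(m1$features$radius, c(0.75, 1.0, 0.5, 0.75, 0.75))
  expect_equal(m1$tolerance, 1.5)
  expect_equal(m1$distances[2, 3], 2.61)   # HBA1-HBA2
  expect_equal(m1$distances[1, 2], 2.62)   # Hyd-HBA1
  expect_equal(m1$distances[1, 3], 4.79)   # Hyd-HBA2
  expect_equal(m1$distances[1, 4], 5.56)   # Hyd-HBD1
  expect_equal(m1$distances[1, 5], 7.68)   # Hyd-HBD2
  expect_equal(sum(upper.tri(m1$distances)), choose(5, 2))
  for (m in models) {
    expect_equal(m$distances, t(m$distances))
    expect_true(all(diag(m$distances) == 0))
    expect_true(all(m$features$radius > 0))
  }
})

test_that("pharmacophore models round-trip through JSON", {
  m1 <- suppressWarnings(builtin_models())$model1
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore_json(m1, path)
  back <- read_pharmacophore_json(path)
  expect_equal(back$distances, m1$distances, ignore_attr = TRUE)
  expect_equal(back$features$kind, m1$features$kind)
  expect_equal(back$tolerance, m1$tolerance)
})

test_that("feature perception honours flags and perceives bonded chemistry", {
  # pre-flagged molecules pass their flags through verbatim
  mol <- make_motif_molecule()
  feats <- perceive_features(mol)
  expect_equal(feats$kind, c("hydrophobic", "hba", "hba", "hbd", "hbd"))
  expect_equal(as.matrix(feats[, c("x", "y", "z")]), mol$coords[1:5, ],
               ignore_attr = TRUE)
  # carbonyl + hydroxyl toy: C(=O) and O-H elsewhere
  toy <- molecule3d(
    "toy", c("C", "O", "C", "O", "H"),
    rbind(c(0, 0, 0), c(1.23, 0, 0), c(4, 0, 0), c(5.4, 0, 0), c(5.9, 0.9, 0)),
    bonds = rbind(c(1, 2, 2), c(3, 4, 1), c(4, 5, 1)))
  tf <- perceive_features(toy)
  expect_equal(sum(tf$kind == "hba"), 1)
  expect_equal(tf[tf$kind == "hba", c("x", "y", "z")],
               data.frame(x = 1.23, y = 0, z = 0), ignore_attr = TRUE)
  expect_equal(sum(tf$kind == "hbd"), 1)
  expect_equal(tf$x[tf$kind == "hbd"], 5.4)
  # six flagged-free ring carbons collapse to one hydrophobic centroid
  ang <- 2 * pi * (0:5) / 6
  ring <- molecule3d("ring", rep("C", 6),
                     cbind(1.4 * cos(ang), 1.4 * sin(ang), 0),
                     bonds = cbind(1:6, c(2:6, 1), 1L))
  rf <- perceive_features(ring)
  expect_equal(nrow(rf), 1)
  expect_equal(rf$kind, "hydrophobic")
  expect_equal(unlist(rf[, c("x", "y", "z")]), c(0, 0, 0),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(perceive_features(molecule3d("x", "C", rbind(c(0, 0, 0)))),
               "flags nor bonds")
})

test_that("matching accepts planted geometry and rejects broken tolerances", {
  m1 <- suppressWarnings(builtin_models())$model1
  mol <- make_motif_molecule(extra_atoms = 6, seed = 2)
  res <- match_pharmacophore(perceive_features(mol), m1)
  expect_true(res$matched)
  expect_equal(res$fit_score, 1, tolerance = 0.01)
  expect_lt(res$max_deviation, 0.05)
  # perturb one feature along the Hyd-HBD2 axis by +2 A (> 1.5 tolerance)
  mol2 <- make_motif_molecule(seed = 3)
  dir <- mol2$coords[5, ] - mol2$coords[1, ]
  mol2$coords[5, ] <- mol2$coords[5, ] + 2 * dir / sqrt(sum(dir^2))
  res2 <- match_pharmacophore(perceive_features(mol2), m1)
  expect_false(res2$matched)
  expect_equal(res2$fit_score, 0)
  expect_error(match_pharmacophore(perceive_features(mol),
                                   local({
                                     m <- m1
                                     m$features <- m$features[rep(1, 9), ]
                                     m$distances <- matrix(0, 9, 9)
                                     m
                                   })), "8 features")
})

test_that("matching equals brute-force assignment enumeration on 4-feature toys", {
  m10 <- suppressWarnings(builtin_models())$model10  # 4 features
  set.seed(7)
  agree <- 0
  for (i in 1:20) {
    n_f <- sample(4:7, 1)
    feats <- data.frame(
      kind = sample(c("hba", "hbd"), n_f, replace = TRUE),
      x = runif(n_f, -6, 6), y = runif(n_f, -6, 6), z = runif(n_f, -6, 6),
      anchor = as.character(seq_len(n_f)))
    got <- match_pharmacophore(feats, m10)$matched
    want <- r_match_bruteforce(feats, m10)
    expect_equal(got, want)
    agree <- agree + got
  }
})

test_that("matching is invariant to rigid motion and monotone in tolerance", {
  m1 <- suppressWarnings(builtin_models())$model1
  mol <- make_motif_molecule(jitter = 0.25, seed = 5)
  set.seed(6)
  R <- random_rotation()
  mol_t <- transform_molecule(mol, R, c(11, -4, 3))
  r1 <- match_pharmacophore(perceive_features(mol), m1)
  r2 <- match_pharmacophore(perceive_features(mol_t), m1)
  expect_equal(r1$matched, r2$matched)
  expect_equal(r1$fit_score, r2$fit_score, tolerance = 1e-9)
  # a super-tolerant model matches whenever the strict one does
  m_loose <- m1; m_loose$tolerance <- 3.0
  for (seed in 1:10) {
    molj <- make_motif_molecule(jitter = 0.6, seed = seed)
    strict <- match_pharmacophore(perceive_features(molj), m1)$matched
    loose <- match_pharmacophore(perceive_features(molj), m_loose)$matched
    if (strict) expect_true(loose)
  }
})

test_that("screening crosses hits with activity labels, order-invariantly", {
  m1 <- suppressWarnings(builtin_models())$model1
  hits <- lapply(1:6, function(i) make_motif_molecule(sprintf("h%d", i),
                                                      jitter = 0.05, seed = i))
  set.seed(30)
  misses <- lapply(1:6, function(i) {
    molecule3d(sprintf("m%d", i), c("C", "O", "N"),
               matrix(runif(9, -4, 4), 3, 3),
               flags = list("hydrophobic", "hba", "hbd"))
  })
  res <- screen_pharmacophore(c(hits, misses),
                              c(rep(TRUE, 6), rep(FALSE, 6)), m1)
  expect_equal(res$metrics$mcc, 1)
  expect_equal(res$metrics$tpr, 1)
  expect_equal(res$hits, c(rep(TRUE, 6), rep(FALSE, 6)))
  # conformer order inside a compound does not change the outcome
  confs_a <- list(misses[[1]], hits[[1]])
  confs_b <- list(hits[[1]], misses[[1]])
  ra <- screen_pharmacophore(list(confs_a), TRUE, m1)
  rb <- screen_pharmacophore(list(confs_b), TRUE, m1)
  expect_equal(ra$hits, rb$hits)
  expect_error(screen_pharmacophore(list(), logical(0), m1), "empty")
})
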