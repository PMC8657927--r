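# Independent reference implementations used as oracles. These mirror the
# documented rules with straightforward loops and stay independent of the
# production code paths they check.

# per-point probe energy: naive double loop over points x atoms
r_probe_energy <- function(mol, pts, probe, params = element_parameters()) {
  idx <- match(mol$elements, params$element)
  idx[is.na(idx)] <- match("*", params$element)
  hbflag <- vapply(mol$flags, function(f) {
    if ("hba" %in% f) 1L else if ("hbd" %in% f) 2L else 0L
  }, integer(1))
  want <- switch(probe$hb_role, none = 0L, acceptor = 2L, donor = 1L)
  # idealized direction: away from mean bonded neighbour / centroid
  ctr <- colMeans(mol$coords)
  nb <- vector("list", nrow(mol$coords))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  hdir <- t(vapply(seq_len(nrow(mol$coords)), function(i) {
    ref <- if (length(nb[[i]])) colMeans(mol$coords[nb[[i]], , drop = FALSE]) else ctr
    v <- mol$coords[i, ] - ref
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) v / nv else c(0, 0, 0)
  }, numeric(3)))
  out <- matrix(0, nrow(pts), 3)
  for (p in seq_len(nrow(pts))) {
    for (a in seq_len(nrow(mol$coords))) {
      d <- pts[p, ] - mol$coords[a, ]
      r2 <- sum(d^2)
      if (r2 < 0.01) { out[p, 1] <- out[p, 1] + 5; next }
      rm_ <- (params$rmin[idx[a]] + probe$lj_rmin) / 2
      em <- sqrt(params$epsilon[idx[a]] * probe$lj_epsilon)
      s6 <- (rm_^2 / r2)^3
      out[p, 1] <- out[p, 1] + em * (s6^2 - 2 * s6)
      out[p, 2] <- out[p, 2] +
        332.06 * probe$charge * mol$charges[a] / (4 * r2)
      if (want != 0 && hbflag[a] == want) {
        t2 <- probe$hb_rmin^2 / r2
        cc <- max(0, sum(d * hdir[a, ]) / sqrt(r2))
        out[p, 3] <- out[p, 3] +
          probe$hb_epsilon * (2 * t2^3 - 3 * t2^2) * cc^2
      }
    }
  }
  out
}

# greedy energy/spread node selection, step by step
r_select_nodes <- function(coords, energy, max_nodes, w, dmax) {
  n <- nrow(coords)
  emax <- abs(min(energy))
  if (emax == 0) emax <- 1
  sel <- which.min(energy)
  dmin <- sqrt(rowSums(sweep(coords, 2L, coords[sel, ])^2))
  while (length(sel) < min(max_nodes, n)) {
    score <- (1 - w) * abs(energy) / emax + w * dmin / dmax
    score[sel] <- -Inf
    nxt <- which.max(score)
    sel <- c(sel, nxt)
    dmin <- pmin(dmin, sqrt(rowSums(sweep(coords, 2L, coords[nxt, ])^2)))
  }
  sel
}

# exhaustive correlogram: all probe pairs, all node pairs
r_macc_bruteforce <- function(nodes_by_probe, bin_width, max_distance) {
  pairs <- c("DRY-DRY", "O-O", "N1-N1", "TIP-TIP", "DRY-O", "DRY-N1",
             "DRY-TIP", "O-N1", "O-TIP", "N1-TIP")
  n_bins <- floor(max_distance / bin_width + 1e-9)
  vals <- numeric(0)
  for (pp in pairs) {
    ab <- strsplit(pp, "-")[[1]]
    na_ <- nodes_by_probe[[ab[1]]]; nb_ <- nodes_by_probe[[ab[2]]]
    block <- setNames(numeric(n_bins), paste0(pp, "|", seq_len(n_bins) - 1))
    if (!is.null(na_) && !is.null(nb_) && nrow(na_) > 0 && nrow(nb_) > 0) {
      for (i in seq_len(nrow(na_))) {
        jr <- if (ab[1] == ab[2]) seq_len(nrow(nb_))[-seq_len(i)] else
          seq_len(nrow(nb_))
        for (j in jr) {
          dd <- sqrt(sum((unlist(na_[i, c("x", "y", "z")]) -
                          unlist(nb_[j, c("x", "y", "z")]))^2))
          b <- floor(dd / bin_width)
          if (b >= 0 && b < n_bins) {
            pr <- na_$energy[i] * nb_$energy[j]
            if (pr > block[b + 1]) block[b + 1] <- pr
          }
        }
      }
    }
    vals <- c(vals, block)
  }
  vals
}

# literal leave-one-out PRESS through n refits of fit_pls
r_loo_press <- function(X, y, nlv, scale_x = FALSE) {
  press <- 0
  for (i in seq_len(nrow(X))) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_latent = nlv,
                   scale_x = scale_x)
    press <- press + (y[i] - predict(fit, X[i, , drop = FALSE]))^2
  }
  press
}

# random node set over a handful of probes
random_node_sets <- function(n_total, seed) {
  set.seed(seed)
  probes <- c("DRY", "O", "N1", "TIP")
  counts <- c(rmultinom(1, n_total, rep(0.25, 4)))
  out <- list()
  for (k in seq_along(probes)) {
    nk <- counts[k]
    out[[probes[k]]] <- data.frame(
      probe = rep(probes[k], nk),
      x = runif(nk, -8, 8), y = runif(nk, -8, 8), z = runif(nk, -8, 8),
      energy = -runif(nk, 0.2, 5)
    )
  }
  out
}

# exhaustive assignment search for pharmacophore matching (<= 4 features)
r_match_bruteforce <- function(features, model) {
  m <- nrow(model$features)
  cand <- lapply(seq_len(m), function(i)
    which(features$kind == model$features$kind[i]))
  fxyz <- as.matrix(features[, c("x", "y", "z")])
  fdist <- as.matrix(dist(fxyz))
  combos <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(combos))) {
    a <- as.integer(combos[r, ])
    if (anyDuplicated(a)) next
    ok <- TRUE
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (abs(fdist[a[i], a[j]] - model$distances[i, j]) > model$tolerance) {
        ok <- FALSE; break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# planted 5-feature molecule at the final model's exact distances
make_motif_molecule <- function(id = "motif", jitter = 0, extra_atoms = 0,
                                seed = 1) {
  set.seed(seed)
  xyz <- grindqsar:::.MOTIF_XYZ + matrix(rnorm(15, sd = jitter), 5, 3)
  elements <- c("C", "O", "O", "N", "N")
  flags <- list("hydrophobic", "hba", "hba", "hbd", "hbd")
  if (extra_atoms > 0) {
    xyz <- rbind(xyz, matrix(rnorm(3 * extra_atoms, sd = 3), ncol = 3))
    elements <- c(elements, rep("C", extra_atoms))
    flags <- c(flags, rep(list(character(0)), extra_atoms))
  }
  molecule3d(id, elements, xyz, flags = flags)
}
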