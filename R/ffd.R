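# Fractional-factorial-design variable selection: variables whose
# exclusion does not degrade the cross-validated error are removed,
# cycle by cycle, with dummy (phantom) variables as a noise yardstick.

#' FFD variable selection
#'
#' Per cycle: `ceiling(dummy_fraction * p)` dummy variables are appended;
#' a balanced two-level design of `design_multiplier * (p + dummies)` rows
#' is drawn in which each (real or dummy) variable is included in exactly
#' half the rows; for every row the SDEP of a PLS model restricted to the
#' included real variables is computed by cross-validation; each
#' variable's effect is `mean SDEP(rows excluding it) - mean SDEP(rows
#' including it)`, so helpful variables have positive effects. Dummies are
#' inert, so the mean absolute dummy effect estimates the noise floor of
#' the effects and is reported per cycle.
#'
#' Under the default `drop_rule = "nonhelpful"` a real variable is removed
#' when its effect is negative -- excluding it does not degrade the
#' cross-validated error. The conservative `"harmful"` variant removes
#' only variables whose exclusion helps more than the dummy noise floor
#' (effect below `-mean(|dummy effects|)`); it prunes far less. Survivors
#' feed the next cycle. Deterministic for a fixed seed.
#'
#' @param X numeric matrix, compounds x variables (>= 10 variables).
#' @param y response.
#' @param n_latent latent variables of the evaluation models.
#' @param cycles number of FFD cycles (default 2; 0 returns the identity
#'   mask).
#' @param dummy_fraction dummies as a fraction of the live variable count
#'   (default 0.2).
#' @param design_multiplier design rows per (variable + dummy)
#'   (default 6; more rows sharpen the effect estimates).
#' @param drop_rule `"nonhelpful"` (default) or `"harmful"`, see above.
#' @param seed integer seed for the designs.
#' @param scheme,k cross-validation scheme forwarded to
#'   [cross_validate()] (default LOO).
#' @param scale_x as in [fit_pls()].
#' @return list of class `ffd_result`: logical `retained` mask over the
#'   input columns, per-cycle statistics (`q2`, `r2`, `sdep`, variable
#'   count, dummy noise floor) and `n_cycles`.
#' @export
ffd_select <- function(X, y, n_latent = 2, cycles = 2, dummy_fraction = 0.2,
                       design_multiplier = 6,
                       drop_rule = c("nonhelpful", "harmful"),
                       seed = 1, scheme = "loo", k = 5, scale_x = FALSE) {
  drop_rule <- match.arg(drop_rule)
  X <- as.matrix(X)
  p0 <- ncol(X)
  if (p0 < 10L) stop("FFD needs at least 10 variables")
  retained <- rep(TRUE, p0)
  stats_fun <- function(mask, dummy_scale = NA_real_) {
    cv <- cross_validate(X[, mask, drop = FALSE], y, n_latent = n_latent,
                         scheme = scheme, k = k, seed = seed,
                         scale_x = scale_x)
    fit <- fit_pls(X[, mask, drop = FALSE], y, n_latent = n_latent,
                   scale_x = scale_x)
    c(q2 = cv$q2, r2 = fit$r2, sdep = cv$sdep, n_vars = sum(mask),
      dummy_scale = dummy_scale)
  }
  cycle_stats <- list(stats_fun(retained))

  for (cy in seq_len(cycles)) {
    live <- which(retained)
    p <- length(live)
    if (p < 2L) break
    n_dummy <- ceiling(dummy_fraction * p)
    n_tot <- p + n_dummy
    n_rows <- design_multiplier * n_tot
    set.seed(seed + cy)  # per-cycle design stream
    design <- vapply(seq_len(n_tot), function(j)
      sample(rep(c(TRUE, FALSE), length.out = n_rows)),
      logical(n_rows))
    sdep_row <- vapply(seq_len(n_rows), function(r) {
      inc <- live[design[r, seq_len(p)]]
      if (length(inc) < 1L) return(NA_real_)
      cross_validate(X[, inc, drop = FALSE], y, n_latent = n_latent,
                     scheme = scheme, k = k, seed = seed,
                     scale_x = scale_x)$sdep
    }, numeric(1))
    ok <- is.finite(sdep_row)
    effect <- vapply(seq_len(n_tot), function(j) {
      inc <- design[, j] & ok
      exc <- (!design[, j]) & ok
      mean(sdep_row[exc]) - mean(sdep_row[inc])
    }, numeric(1))
    dummy_scale <- mean(abs(effect[(p + 1L):n_tot]))
    drop_ <- if (drop_rule == "nonhelpful") effect[seq_len(p)] < 0
             else effect[seq_len(p)] < -dummy_scale
    if (all(drop_))
      stop("FFD removed every variable; effects: ",
           paste(sprintf("%.3f", effect[seq_len(p)]), collapse = ", "))
    retained[live[drop_]] <- FALSE
    cycle_stats[[cy + 1L]] <- stats_fun(retained, dummy_scale)
  }
  tab <- as.data.frame(do.call(rbind, cycle_stats))
  tab$cycle <- seq_len(nrow(tab)) - 1L
  structure(list(retained = retained, cycle_stats = tab,
                 n_cycles = nrow(tab) - 1L),
            class = "ffd_result")
}

#' @export
print.ffd_result <- function(x, ...) {
  cat(sprintf("<ffd_result> %d cycle(s), %d variable(s) retained\n",
              x$n_cycles, sum(x$retained)))
  print(x$cycle_stats, row.names = FALSE)
  invisible(x)
}

#' Signed coefficient correlogram of a fitted model
#'
#' Returns the regression coefficients on the original variable scale,
#' grouped by probe pair and ordered by distance bin -- positive values
#' flag variables directly correlated with potency, negative values
#' inversely correlated ones.
#'
#' @param model a `pls_model`.
#' @param labels variable labels (e.g. from [descriptor_matrix()]); must
#'   match the coefficient count.
#' @return data.frame `label`, `probe_pair`, `bin_low`, `bin_high`,
#'   `coefficient`, ordered by probe pair then distance.
#' @export
coefficient_correlogram <- function(model, labels) {
  coefs <- model$coefficients
  if (length(labels) != length(coefs))
    stop("labels and coefficients differ in length")
  m <- regmatches(labels,
                  regexec("^([A-Z0-9]+-[A-Z0-9]+) \\[([0-9.]+)-([0-9.]+) A\\]$",
                          labels))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("unparseable label(s): ", labels[bad][1])
  out <- data.frame(
    label = labels,
    probe_pair = vapply(m, `[`, character(1), 2L),
    bin_low = as.numeric(vapply(m, `[`, character(1), 3L)),
    bin_high = as.numeric(vapply(m, `[`, character(1), 4L)),
    coefficient = coefs,
    stringsAsFactors = FALSE
  )
  out[order(match(out$probe_pair, .PROBE_PAIRS), out$bin_low), ]
}

#' Serialize a fitted model (with masks and scalers) to JSON
#'
#' @param model a `pls_model`.
#' @param path output JSON path.
#' @param retained optional logical FFD mask to store alongside.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, retained = NULL) {
  obj <- list(
    n_latent = model$n_latent, coefficients = model$coefficients,
    intercept = model$intercept, x_center = model$x_center,
    x_scale = model$x_scale, y_center = model$y_center,
    scale_x = model$scale_x, r2 = model$r2,
    variable_names = model$variable_names, retained = retained
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
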