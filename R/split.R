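# Diversity-based train/test splitting by MaxMin subset selection on a
# descriptor table (Gillet-style diverse subset selection).

#' Diverse train/test split (MaxMin selection)
#'
#' Descriptors are standardized internally (zero mean, unit variance;
#' constant columns dropped). The training set is grown greedily: a seeded
#' random start, then the compound maximising its minimum Euclidean
#' distance to the already-selected set is added until
#' `ceiling(fraction_train * n)` compounds are selected. Ties are broken by
#' row order, making the split deterministic for a fixed seed.
#'
#' @param descriptors numeric matrix or data.frame, one row per compound,
#'   with rownames used as compound ids (row index otherwise).
#' @param fraction_train fraction of compounds in the training set,
#'   in (0, 1); default 0.8.
#' @param seed integer seed for the starting compound.
#' @return list with `train_ids`, `test_ids`, `fraction_train`, and
#'   `order` (the MaxMin selection sequence).
#' @export
diverse_split <- function(descriptors, fraction_train = 0.8, seed = 1) {
  X <- as.matrix(descriptors)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 compounds to split")
  if (!(fraction_train > 0 && fraction_train < 1))
    stop("fraction_train must be in (0, 1)")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  keep <- apply(X, 2L, function(col) sd(col) > 0)
  if (!any(keep)) stop("all descriptor columns are constant")
  Z <- scale(X[, keep, drop = FALSE])

  n_train <- ceiling(fraction_train * n)
  d <- as.matrix(stats::dist(Z))
  withr_seed <- function(expr) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  start <- withr_seed(sample.int(n, 1L))

  selected <- start
  dmin <- d[, start]
  while (length(selected) < n_train) {
    dmin_cand <- dmin
    dmin_cand[selected] <- -Inf
    nxt <- which.max(dmin_cand)  # ties -> lowest row index
    selected <- c(selected, nxt)
    dmin <- pmin(dmin, d[, nxt])
  }
  list(train_ids = ids[selected], test_ids = ids[-selected],
       fraction_train = fraction_train, order = ids[selected])
}
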