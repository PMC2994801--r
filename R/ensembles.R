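# Deterministic per-network seed derived from the run seed and a stream
# index; kept inside 32-bit integer range.
.derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + 104729 * idx) %% 2147483629 + 1)
}

#' Split chains into cross-validation folds
#'
#' Chains (never residues) are the split unit: each chain lands in exactly
#' one test fold. Fold residue totals are balanced greedily -- chains are
#' shuffled (seeded), stably sorted by length, and each is assigned to the
#' currently lightest fold -- so the residue imbalance between folds never
#' exceeds the longest chain.
#'
#' @param chains Tibble with a `chain_id` column and either a `length`
#'   column or a list-column `chain` of `bturn_chain` objects.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Tibble `chain_id`, `length`, `fold`.
#' @export
make_folds <- function(chains, k = 10, seed = 1) {
  chains <- tibble::as_tibble(chains)
  if (!"length" %in% names(chains)) {
    chains$length <- vapply(chains$chain, nrow, integer(1))
  }
  n <- nrow(chains)
  if (n < k) stop(sprintf("need at least %d chains for %d folds", k, k))
  ord <- withr::with_seed(.derive_seed(seed, 0), sample(n))
  df <- chains[ord, c("chain_id", "length")]
  df <- df[order(-df$length), ]
  totals <- numeric(k)
  fold <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    f <- which.min(totals)
    fold[i] <- f
    totals[f] <- totals[f] + df$length[i]
  }
  df$fold <- fold
  dplyr::arrange(df, match(.data$chain_id, chains$chain_id))
}

# Stack windowed examples for a set of chains at one window size.
.stack_examples <- function(features, labels, ids, w) {
  X <- do.call(rbind, lapply(ids, function(id) {
    encode_windows(features[[id]], w)
  }))
  y <- unlist(labels[ids], use.names = FALSE)
  list(X = X, y = as.integer(y))
}

#' Train the architecture grid across all folds
#'
#' One network per (architecture, fold) combination: trained on the
#' chains outside the fold, epoch-selected on the fold's chains, with the
#' fold test MCC recorded as the network's leave-out performance. The
#' full study grid (5 windows x 4 hidden sizes x 10 folds) yields 200
#' networks.
#'
#' @param labels Named list: chain id -> logical per-residue label vector.
#' @param features Named list: chain id -> feature-track matrix.
#' @param plan Fold plan from [make_folds()].
#' @param grid Architecture tibble from [architecture_grid()].
#' @param seed Integer seed; per-network seeds are derived from it.
#' @param ... Passed to [train_config()] (learning rate, epochs, ...).
#' @return List of `bturn_net`, one per architecture x fold.
#' @export
train_grid <- function(labels, features, plan,
                       grid = architecture_grid(), seed = 1, ...) {
  stopifnot(setequal(names(labels), plan$chain_id),
            setequal(names(features), plan$chain_id))
  nets <- list()
  idx <- 0
  for (a in seq_len(nrow(grid))) {
    w <- grid$window[a]
    h <- grid$hidden_units[a]
    # encode every chain once per window size
    enc <- lapply(plan$chain_id, function(id) encode_windows(features[[id]], w))
    names(enc) <- plan$chain_id
    for (f in sort(unique(plan$fold))) {
      idx <- idx + 1
      test_ids <- plan$chain_id[plan$fold == f]
      train_ids <- plan$chain_id[plan$fold != f]
      Xtr <- do.call(rbind, enc[train_ids])
      ytr <- as.integer(unlist(labels[train_ids], use.names = FALSE))
      Xte <- do.call(rbind, enc[test_ids])
      yte <- as.integer(unlist(labels[test_ids], use.names = FALSE))
      cfg <- train_config(window = w, hidden_units = h,
                          seed = .derive_seed(seed, idx), ...)
      nets[[idx]] <- train_backprop(Xtr, ytr, Xte, yte, cfg, fold = f)
    }
  }
  nets
}

# ranking order: MCC desc, then smaller window, fewer hidden, lower fold
.rank_networks <- function(nets) {
  g <- dplyr::bind_rows(lapply(nets, glance))
  order(-g$leaveout_mcc, g$window, g$hidden_units, g$fold)
}

#' Select an ensemble from trained networks
#'
#' First-layer mode (`mode = "top"`): the `size` networks with the best
#' leave-out MCC across all folds (the study keeps the best 100 of 200).
#' Second-layer mode (`mode = "per_fold"`): the single top-ranked network
#' within each fold subset (one member per fold). Ties break by smaller
#' window, fewer hidden units, lower fold id.
#'
#' @param networks List of `bturn_net` from [train_grid()].
#' @param size Ensemble size for `mode = "top"`.
#' @param mode Selection mode.
#' @return A `bturn_ensemble`: selected members sorted by rank, with all
#'   candidate networks retained for cross-validated scoring.
#' @export
select_ensemble <- function(networks, size = 100,
                            mode = c("top", "per_fold")) {
  mode <- match.arg(mode)
  ord <- .rank_networks(networks)
  ranked <- networks[ord]
  if (mode == "top") {
    if (length(ranked) < size) {
      stop(sprintf("requested ensemble of %d from %d networks", size,
                   length(ranked)))
    }
    members <- ranked[seq_len(size)]
  } else {
    folds <- vapply(ranked, function(n) n$fold, numeric(1))
    keep <- !duplicated(folds)
    members <- ranked[keep]
    members <- members[order(vapply(members, function(n) n$fold,
                                    numeric(1)))]
  }
  structure(list(members = members, mode = mode, pool = networks),
            class = "bturn_ensemble")
}

#' @export
print.bturn_ensemble <- function(x, ...) {
  cat(sprintf("<bturn_ensemble: %d members (%s) of %d networks>\n",
              length(x$members), x$mode, length(x$pool)))
  invisible(x)
}

#' @export
glance.bturn_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(x$members, glance))
}

#' Ensemble score for one chain
#'
#' Unweighted mean of the member networks' scores; each member windows the
#' track at its own window size.
#'
#' @param ensemble A `bturn_ensemble` (or plain list of `bturn_net`).
#' @param track Feature-track matrix for the chain.
#' @param members Optional member subset to average over.
#' @return Per-residue score vector in `[0, 1]`.
#' @export
ensemble_predict <- function(ensemble, track, members = NULL) {
  if (is.null(members)) {
    members <- if (inherits(ensemble, "bturn_ensemble")) ensemble$members
    else ensemble
  }
  scores <- vapply(members, function(net) {
    nn_forward(net, encode_windows(track, net$window))
  }, numeric(nrow(track)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(track))
  rowMeans(scores)
}

#' Cross-validated ensemble scores
#'
#' For every chain, only networks whose training folds exclude it (i.e.
#' networks carrying the chain's own fold id) contribute, so no reported
#' score ever comes from a network that saw the chain. If the selection
#' holds no member for some fold, the best-ranked network of that fold
#' from the candidate pool stands in.
#'
#' @param ensemble A `bturn_ensemble`.
#' @param features Named list: chain id -> track matrix.
#' @param plan Fold plan from [make_folds()].
#' @return Named list: chain id -> per-residue score vector.
#' @export
cv_ensemble_scores <- function(ensemble, features, plan) {
  member_folds <- vapply(ensemble$members, function(n) n$fold, numeric(1))
  pool_ord <- .rank_networks(ensemble$pool)
  out <- list()
  for (f in sort(unique(plan$fold))) {
    members <- ensemble$members[member_folds == f]
    if (length(members) == 0) {
      pool_folds <- vapply(ensemble$pool, function(n) n$fold, numeric(1))
      members <- ensemble$pool[pool_ord[pool_folds[pool_ord] == f][1]]
    }
    for (id in plan$chain_id[plan$fold == f]) {
      out[[id]] <- ensemble_predict(NULL, features[[id]], members = members)
    }
  }
  out[plan$chain_id]
}
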