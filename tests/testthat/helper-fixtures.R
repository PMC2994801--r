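# Shared fixtures and independent oracles. Heavy objects are built once
# per test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_dataset <- function() {
  cached("small_dataset", function() {
    synth_dataset(fixture_spec(n_chains = 12, length_range = c(50, 70),
                               turns_per_chain = 3, seed = 401))
  })
}

small_model <- function() {
  cached("small_model", function() {
    train_layered(small_dataset(),
                  grid = architecture_grid(c(5, 9), c(8, 16)),
                  k = 3, seed = 77, max_epochs = 30)
  })
}

# --- independent oracles -------------------------------------------------

# circular deviation via complex rotation, deliberately different from the
# package's wrap-based arithmetic
oracle_angle_dev <- function(a, b) {
  abs(Arg(exp(1i * (a - b) * pi / 180))) * 180 / pi
}

# rule-by-rule enumeration of the turn-type definitions
oracle_classify <- function(angles, cis3, table = canonical_turn_table(),
                            tol = 30, tol_one = 40) {
  for (k in seq_len(nrow(table))) {
    devs <- c(oracle_angle_dev(angles[1], table$phi1[k]),
              oracle_angle_dev(angles[2], table$psi1[k]),
              oracle_angle_dev(angles[3], table$phi2[k]),
              oracle_angle_dev(angles[4], table$psi2[k]))
    rule_a <- all(devs <= tol_one)
    rule_b <- sum(devs > tol) <= 1
    rule_c <- !table$cis_pro[k] || cis3
    if (rule_a && rule_b && rule_c) return(table$type[k])
  }
  "IV"
}

# naive loop confusion counts
oracle_confusion <- function(scores, labels, threshold = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(scores)) {
    call <- scores[i] >= threshold
    if (call && labels[i]) tp <- tp + 1
    else if (call && !labels[i]) fp <- fp + 1
    else if (!call && !labels[i]) tn <- tn + 1
    else fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# AUC as the normalized Mann-Whitney U with half credit for ties
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

# exhaustive Hobohm-1 verification: result must be an independent set of
# the >threshold similarity graph, greedily maximal under the ranking
oracle_hobohm <- function(records, accepted_ids, threshold, rank_fn,
                          identity_fn) {
  acc <- match(accepted_ids, records$id)
  sim <- function(i, j) identity_fn(records$sequence[i],
                                    records$sequence[j])
  for (a in acc) for (b in acc) {
    if (a < b && sim(a, b) > threshold) return(FALSE)  # not independent
  }
  ord <- order(rank_fn(records))
  chosen <- integer(0)
  for (i in ord) {
    if (all(vapply(chosen, function(j) sim(i, j) <= threshold,
                   logical(1)))) {
      chosen <- c(chosen, i)
    }
  }
  identical(sort(chosen), sort(acc))
}

# toy hamming-style identity for algorithm-level tests (fast, symmetric)
hamming_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- min(length(av), length(bv))
  100 * sum(av[seq_len(n)] == bv[seq_len(n)]) / max(length(av), length(bv))
}

random_chain_records <- function(n, seed) {
  withr::with_seed(seed, {
    base <- vapply(seq_len(ceiling(n / 5)), function(i) {
      paste(sample(c("A", "C", "D", "E", "F", "G"), 30, TRUE),
            collapse = "")
    }, character(1))
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(sample(base, 1), "")[[1]]
      k <- sample(0:12, 1)
      if (k > 0) {
        idx <- sample(30, k)
        s[idx] <- sample(c("A", "C", "D", "E", "F", "G"), k, TRUE)
      }
      paste(s, collapse = "")
    }, character(1))
    chain_records(id = sprintf("R%02d", seq_len(n)), sequence = seqs,
                  resolution = round(runif(n, 1, 3), 2),
                  pdb_length = 30 - sample(0:3, n, TRUE))
  })
}
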