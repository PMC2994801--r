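test_that("fold assignment balances residues and is deterministic", {
  chains <- tibble::tibble(chain_id = sprintf("c%02d", 1:20),
                           length = rep(50, 20))
  plan <- make_folds(chains, k = 10, seed = 3)
  expect_equal(as.integer(table(plan$fold)), rep(2L, 10))
  expect_identical(plan, make_folds(chains, k = 10, seed = 3))
  expect_false(identical(plan$fold,
                         make_folds(chains, k = 10, seed = 4)$fold))

  withr::with_seed(16, {
    varied <- tibble::tibble(chain_id = sprintf("v%02d", 1:17),
                             length = sample(40:200, 17))
    p2 <- make_folds(varied, k = 5, seed = 9)
    totals <- tapply(p2$length, p2$fold, sum)
    expect_lte(max(totals) - min(totals), max(varied$length))
  })
  expect_error(make_folds(chains[1:4, ], k = 10), "at least")
})

test_that("the trained grid has full bookkeeping and no fold overlap", {
  ds <- small_dataset()
  model <- small_model()
  nets <- model$first$g$pool
  # 2 windows x 2 hidden x 3 folds
  expect_length(nets, 12)
  g <- dplyr::bind_rows(lapply(nets, glance))
  expect_true(all(is.finite(g$leaveout_mcc)))
  expect_setequal(unique(g$fold), 1:3)
  expect_setequal(unique(g$window), c(5, 9))
  expect_setequal(unique(g$hidden_units), c(8, 16))
})

test_that("top-k selection separates kept from dropped by MCC", {
  nets <- small_model()$first$g$pool
  ens <- select_ensemble(nets, size = 6)
  kept <- vapply(ens$members, function(n) n$leaveout_mcc, numeric(1))
  all_mcc <- sort(vapply(nets, function(n) n$leaveout_mcc, numeric(1)),
                  decreasing = TRUE)
  expect_equal(sort(kept, decreasing = TRUE), all_mcc[1:6])
  expect_gte(min(kept), max(all_mcc[7:12]))
  expect_error(select_ensemble(nets, size = 99), "99")
})

test_that("per-fold selection returns exactly one member per fold", {
  nets <- small_model()$second$g$pool
  ens <- select_ensemble(nets, mode = "per_fold")
  folds <- vapply(ens$members, function(n) n$fold, numeric(1))
  expect_equal(folds, 1:3)
})

test_that("ties in leave-out MCC break deterministically", {
  base <- small_model()$first$g$pool[[1]]
  fake <- lapply(1:4, function(i) {
    n <- base
    n$leaveout_mcc <- 0.5
    n$window <- c(9, 5, 9, 5)[i]
    n$hidden_units <- c(16, 16, 8, 8)[i]
    n$fold <- i
    n
  })
  ens <- select_ensemble(fake, size = 2)
  expect_equal(vapply(ens$members, function(n) n$window, numeric(1)),
               c(5, 5))
  expect_equal(vapply(ens$members, function(n) n$hidden_units,
                      numeric(1)), c(8, 16))
})

test_that("ensemble prediction is the unweighted member mean", {
  model <- small_model()
  ds <- small_dataset()
  track <- feature_track(ds$profile[[1]], ds$struct[[1]])
  one <- model$first$g$members[[1]]
  solo <- structure(list(members = list(one), mode = "top",
                         pool = list(one)), class = "bturn_ensemble")
  expect_equal(ensemble_predict(solo, track), nn_forward(
    one, encode_windows(track, one$window)))

  two <- model$first$g$members[1:2]
  m1 <- nn_forward(two[[1]], encode_windows(track, two[[1]]$window))
  m2 <- nn_forward(two[[2]], encode_windows(track, two[[2]]$window))
  duo <- structure(list(members = two, mode = "top", pool = two),
                   class = "bturn_ensemble")
  s <- ensemble_predict(duo, track)
  expect_equal(s, (m1 + m2) / 2, tolerance = 1e-12)
  expect_true(all(s >= 0 & s <= 1))
  # averaging never exceeds the most variable member
  expect_lte(stats::var(s), max(stats::var(m1), stats::var(m2)) + 1e-12)
})

test_that("the layered model improves or preserves AUC and stays clean", {
  model <- small_model()
  g <- glance(model)
  expect_gte(g$auc[g$layer == "second"], g$auc[g$layer == "first"] - 0.005)
  audit <- audit_no_leakage(model)
  expect_equal(sum(audit$violations), 0)
})

test_that("cross-validated scores only come from fold-matched networks", {
  model <- small_model()
  ds <- small_dataset()
  features <- stats::setNames(
    purrr::map2(ds$profile, ds$struct, feature_track), ds$chain_id)
  # recompute one chain's cv score from the fold-matched members only
  id <- model$plan$chain_id[1]
  f <- model$plan$fold[model$plan$chain_id == id]
  members <- Filter(function(n) n$fold == f, model$first$g$members)
  if (length(members) == 0) {
    pool <- model$first$g$pool
    ord <- betaturn:::.rank_networks(pool)
    pf <- vapply(pool, function(n) n$fold, numeric(1))
    members <- pool[ord[pf[ord] == f][1]]
  }
  manual <- ensemble_predict(NULL, features[[id]], members = members)
  expect_equal(model$cv_first$g[[id]], manual, tolerance = 1e-12)
})

test_that("a setup without PSSM or structure trains and predicts", {
  ds <- small_dataset()
  model_g <- train_layered(ds, setup = "G",
                           grid = architecture_grid(5, 8),
                           k = 3, seed = 5, max_epochs = 15)
  rep <- predict_chain(model_g, ds$profile[[2]], ds$struct[[2]])
  expect_equal(nrow(rep), nrow(ds$struct[[2]]))
  expect_true(all(rep$turn_score >= 0 & rep$turn_score <= 1))
})

test_that("prediction reports cover every residue and honor thresholds", {
  model <- small_model()
  ds <- small_dataset()
  rep <- predict_chain(model, ds$profile[[3]], ds$struct[[3]])
  expect_equal(nrow(rep), nrow(ds$struct[[3]]))
  expect_identical(rep$call, rep$turn_score >= model$threshold)
  rep61 <- predict_chain(model, ds$profile[[3]], ds$struct[[3]],
                         threshold = 0.61)
  expect_identical(rep61$call, rep61$turn_score >= 0.61)
  expect_lte(sum(rep61$call), sum(rep$call))
  bad <- ds$struct[[3]][1:10, ]
  expect_error(predict_chain(model, ds$profile[[3]], bad), "length")
})

test_that("model serialization round-trips predictions", {
  model <- small_model()
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  write_model(model, dir)
  back <- read_model(dir)
  r1 <- predict_chain(model, ds$profile[[5]], ds$struct[[5]])
  r2 <- predict_chain(back, ds$profile[[5]], ds$struct[[5]])
  expect_equal(r2$turn_score, r1$turn_score, tolerance = 1e-12)
  expect_equal(r2$p3, r1$p3, tolerance = 1e-12)
  expect_equal(back$setup, model$setup)
})

test_that("type-specific networks train and surface in the report", {
  ds <- synth_dataset(fixture_spec(
    n_chains = 9, length_range = c(50, 60), turns_per_chain = 3,
    type_weights = c("I" = 0.6, "II" = 0.4), seed = 811))
  model <- suppressMessages(
    train_layered(ds, grid = architecture_grid(5, 8), k = 3,
                  seed = 6, max_epochs = 10, types = TRUE))
  rep <- predict_chain(model, ds$profile[[1]], ds$struct[[1]])
  expect_true(all(TURN_TYPES %in% names(rep)))
  # the planted, fold-covered types carry real scores
  expect_true(all(rep$I >= 0 & rep$I <= 1))
  expect_true(all(rep$II >= 0 & rep$II <= 1))
  # a type absent from the set is skipped and reported as NA
  expect_true(all(is.na(rep$VIb)))
})
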