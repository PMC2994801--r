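tab <- canonical_turn_table()

center_angles <- function(type) {
  r <- tab[tab$type == type, ]
  c(r$phi1, r$psi1, r$phi2, r$psi2)
}

test_that("canonical centers classify to their own type", {
  for (ty in tab$type) {
    cis <- tab$cis_pro[tab$type == ty]
    expect_identical(classify_turn_type(center_angles(ty),
                                        cis_pro_at_3 = cis), ty)
  }
})

test_that("the single-angle 40-degree allowance works as specified", {
  a <- center_angles("I")
  # one deviation of 35 keeps the type
  expect_identical(classify_turn_type(a + c(0, 0, 0, 35)), "I")
  # two deviations above 30 lose it
  expect_identical(classify_turn_type(a + c(0, 35, 0, 35)), "IV")
  # a single deviation above 40 loses it
  expect_identical(classify_turn_type(a + c(0, 0, 0, 41)), "IV")
  expect_identical(classify_turn_type(a + c(0, 0, 0, 39.9)), "I")
})

test_that("cis-proline is required for the VIa types", {
  expect_identical(classify_turn_type(center_angles("VIa1"),
                                      cis_pro_at_3 = FALSE), "IV")
  expect_identical(classify_turn_type(center_angles("VIa2"),
                                      cis_pro_at_3 = FALSE), "IV")
  expect_identical(classify_turn_type(center_angles("VIa1"),
                                      cis_pro_at_3 = TRUE), "VIa1")
  # VIb does not carry the requirement by default, but can
  expect_identical(classify_turn_type(center_angles("VIb")), "VIb")
  tab_cis <- canonical_turn_table(vib_requires_cis = TRUE)
  expect_identical(classify_turn_type(center_angles("VIb"),
                                      table = tab_cis), "IV")
})

test_that("deviations are measured on the circle", {
  a <- center_angles("VIb")         # psi2 = 160
  a[4] <- -175                      # 25 degrees away through the seam
  expect_identical(classify_turn_type(a), "VIb")
})

test_that("multi-type matches break by precedence, or best fit on request", {
  # inside both VIa windows: VIa1 off by (40,0,20,0), VIa2 by (20,0,10,0)
  a <- c(-100, 120, -70, 0)
  expect_identical(classify_turn_type(a, cis_pro_at_3 = TRUE), "VIa1")
  expect_identical(classify_turn_type(a, cis_pro_at_3 = TRUE,
                                      best_fit = TRUE), "VIa2")
})

test_that("undefined angles are an error", {
  expect_error(classify_turn_type(c(NA, 0, 0, 0)), "undefined")
})

test_that("planted turns across all defined types are recovered", {
  withr::with_seed(61, {
    n <- 200
    types <- sample(tab$type, n, replace = TRUE)
    for (i in seq_len(n)) {
      ang <- betaturn:::.sample_plant_angles(types[i], 25, tab)
      cis <- tab$cis_pro[tab$type == types[i]]
      expect_identical(classify_turn_type(ang, cis_pro_at_3 = cis),
                       types[i])
    }
  })
})

test_that("shrinking the tolerance never rescues a type IV", {
  withr::with_seed(71, {
    angles <- matrix(runif(4 * 300, -180, 180), ncol = 4)
    t30 <- classify_turn_type(angles, cis_pro_at_3 = TRUE)
    t20 <- classify_turn_type(angles, cis_pro_at_3 = TRUE,
                              tol = 20, tol_one = 30)
    expect_true(all(t20[t30 == "IV"] == "IV"))
  })
})

test_that("assign_turns recovers planted instances and honors exclusions", {
  withr::with_seed(81, {
    plant <- plant_turn_chain(40, turns = tibble::tibble(
      start = c(8, 20, 30), type = c("II", "I'", "VIa1")), jitter = 12)
    ann <- assign_turns(plant$chain)
    inst <- turn_instances(ann)
    expect_equal(inst$start, c(8, 20, 30))
    expect_equal(inst$type, c("II", "I'", "VIa1"))
    expect_identical(annotation_table(ann), annotation_table(plant$truth))

    # helix at a central residue suppresses that turn
    mask <- rep(FALSE, 40)
    mask[21] <- TRUE                 # i+1 of the turn starting at 20
    ann2 <- assign_turns(plant$chain, helix_mask = mask)
    expect_equal(turn_instances(ann2)$start, c(8, 30))
  })
})

test_that("an extended strand contains no beta-turn", {
  ch <- build_backbone_from_torsions(
    tibble::tibble(phi = rep(-120, 20), psi = rep(130, 20)))
  ann <- assign_turns(ch)
  expect_equal(sum(ann$in_turn), 0)
  expect_equal(nrow(turn_instances(ann)), 0)
})

test_that("incomplete residues break candidate windows", {
  withr::with_seed(91, {
    plant <- plant_turn_chain(20, turns = tibble::tibble(start = 8,
                                                         type = "I"))
    ch <- plant$chain
    ch$ca_x[9] <- NA_real_
    ch <- new_backbone_chain(ch[, setdiff(names(ch), "complete")],
                             chain_id = "A")
    ann <- assign_turns(ch)
    expect_equal(nrow(turn_instances(ann)), 0)
  })
})

test_that("overlapping instances give multi-position sets (turn of five)", {
  withr::with_seed(101, {
    ov <- plant_turn_chain(14, turns = tibble::tibble(
      start = c(5, 6), type = c("VIII", "VIa2")), jitter = 0,
      overlap = TRUE)
    ann <- assign_turns(ov$chain)
    expect_equal(turn_instances(ann)$type, c("VIII", "VIa2"))
    pos <- position_labels(ann)$positions
    expect_equal(pos[[6]], c(1, 2))
    expect_equal(pos[[8]], c(3, 4))
    expect_equal(sum(ann$in_turn), 5)    # five-residue compound turn
    expect_equal(pos[[2]], integer(0))   # non-turn residue: empty set

    labs <- label_sets(ann)
    expect_equal(sum(labs$general), 5)
    expect_equal(sum(labs$type[["VIII"]]), 4)
    expect_equal(sum(labs$type[["VIa2"]]), 4)
    expect_equal(sum(labs$type[["I"]]), 0)
    expect_equal(which(labs$position[[1]]), c(5, 6))
  })
})

test_that("a single instance yields positions 1..4 in order", {
  withr::with_seed(111, {
    plant <- plant_turn_chain(12, turns = tibble::tibble(start = 5,
                                                         type = "I"))
    ann <- assign_turns(plant$chain)
    pos <- position_labels(ann)$positions
    expect_equal(pos[5:8], list(1L, 2L, 3L, 4L))
    labs <- label_sets(ann)
    expect_equal(sum(labs$general), 4)
    expect_equal(sum(labs$type[["I"]]), 4)
    expect_equal(sum(labs$type[["II"]]), 0)
  })
})

test_that("an empty annotation yields all-negative label tracks", {
  ch <- build_backbone_from_torsions(
    tibble::tibble(phi = rep(-120, 10), psi = rep(130, 10)))
  labs <- label_sets(assign_turns(ch))
  expect_false(any(labs$general))
  expect_false(any(unlist(labs$type)))
  expect_false(any(unlist(labs$position)))
})
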