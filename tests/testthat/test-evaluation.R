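test_that("fold partitions are near-equal, exhaustive and reproducible", {
  ids <- sprintf("m%04d", 1:10)
  f <- make_folds(ids, k = 5, seed = 1)
  expect_identical(sort(unique(f$fold)), 1:5)
  expect_identical(as.integer(table(f$fold)), rep(2L, 5))
  expect_identical(sort(f$marker_id), sort(ids))

  expect_identical(make_folds(ids, 5, seed = 7), make_folds(ids, 5, seed = 7))
  expect_false(identical(
    make_folds(ids, 5, seed = 7)$marker_id,
    make_folds(ids, 5, seed = 8)$marker_id
  ))

  # the 20-fold split of 4502 mapped markers gives folds of 225-226
  big <- make_folds(sprintf("s%04d", 1:4502), k = 20, seed = 1)
  expect_identical(sort(unique(as.vector(table(big$fold)))), c(225L, 226L))

  expect_error(make_folds(ids, 1, seed = 1), "at least 2")
  expect_error(make_folds(ids, 11, seed = 1), "not exceed")
})

test_that("efficiency and accuracy reproduce hand-computed ratios", {
  # 200 masked, 179 placed, 177 on the right linkage group
  truth <- tibble::tibble(
    marker_id = sprintf("m%03d", 1:200),
    linkage_group = "LG1",
    position = as.numeric(1:200)
  )
  placements <- tibble::tibble(
    marker_id = truth$marker_id,
    status = c(rep("placed", 179), rep("unplaced", 21)),
    linkage_group = c(rep("LG1", 177), rep("LG2", 2), rep(NA, 21)),
    position = c(as.numeric(1:177) + 0.5, 5, 6, rep(NA, 21))
  )
  sc <- lodemap:::score_fold(placements, truth)
  expect_equal(sc$efficiency, 89.5)
  expect_equal(round(sc$accuracy, 2), 98.88)
  expect_equal(sc$mean_abs_distance, 0.5)
  expect_equal(sc$pearson_r, 1)
})

test_that("identical anchor twins give perfect recovery", {
  set.seed(13)
  n <- 400
  pos <- seq(5, 50, by = 5)
  cols <- lapply(pos, function(p) rbinom(n, 2, 0.5))
  # per position: two identical anchors plus one identical candidate
  g <- gm(
    do.call(cbind, lapply(cols, function(v) cbind(v, v, v))),
    marker_ids = as.vector(t(outer(
      seq_along(pos), c("a", "b", "c"),
      function(i, s) sprintf("p%02d_%s", i, s)
    )))
  )
  map <- tibble::tibble(
    marker_id = as.vector(vapply(
      seq_along(pos), function(i) sprintf("p%02d_%s", i, c("a", "b")),
      character(2)
    )),
    linkage_group = "LG1",
    position = rep(pos, each = 2)
  )
  cand <- sprintf("p%02d_c", seq_along(pos))
  pl <- place_markers(g, map, cand, threshold = 0.1)
  truth <- tibble::tibble(
    marker_id = cand, linkage_group = "LG1", position = pos
  )
  sc <- lodemap:::score_fold(pl, truth)
  expect_equal(sc$efficiency, 100)
  expect_equal(sc$accuracy, 100)
  expect_equal(sc$mean_abs_distance, 0)
  expect_true(all(pl$top_r2 == 1))
})

test_that("cross-validation bookkeeping and reproducibility hold", {
  sim <- small_sim()
  cv <- suppressWarnings(
    cross_validate(sim$genotypes, sim$truth_map, k = 5, seed = 11)
  )
  expect_identical(nrow(cv$per_fold), 5L)
  # fold memberships partition the mapped set
  expect_identical(
    sort(cv$folds$marker_id), sort(sim$truth_map$marker_id)
  )
  expect_identical(anyDuplicated(cv$folds$marker_id), 0L)
  # counting identities per fold
  expect_true(all(cv$per_fold$n_correct <= cv$per_fold$n_placed))
  expect_true(all(cv$per_fold$n_placed <= cv$per_fold$n_masked))
  expect_true(all(
    cv$per_fold$efficiency >= 0 & cv$per_fold$efficiency <= 100
  ))
  expect_true(all(
    is.na(cv$per_fold$accuracy) |
      (cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 100)
  ))
  cv2 <- suppressWarnings(
    cross_validate(sim$genotypes, sim$truth_map, k = 5, seed = 11)
  )
  expect_identical(cv$per_fold, cv2$per_fold)
  expect_identical(glance(cv), glance(cv2))
})

test_that("no placements yields zero efficiency and flagged accuracy", {
  set.seed(17)
  n <- 120
  # anchors correlated with each other, candidates independent of them
  base <- rbinom(n, 2, 0.5)
  g <- gm(
    cbind(base, base, rbinom(n, 2, 0.5), rbinom(n, 2, 0.5)),
    marker_ids = c("a1", "a2", "u1", "u2")
  )
  map <- tibble::tibble(
    marker_id = c("a1", "a2"), linkage_group = "LG1", position = c(0, 2)
  )
  pl <- place_markers(g, map, c("u1", "u2"), threshold = 0.5)
  truth <- tibble::tibble(
    marker_id = c("u1", "u2"), linkage_group = "LG1", position = c(1, 1.5)
  )
  sc <- lodemap:::score_fold(pl, truth)
  expect_equal(sc$efficiency, 0)
  expect_identical(sc$accuracy, NA_real_)
})

test_that("a fold emptying a small linkage group warns but still runs", {
  set.seed(19)
  n <- 100
  base1 <- rbinom(n, 2, 0.5)
  base2 <- rbinom(n, 2, 0.5)
  jig <- function(v) {
    i <- sample(n, 6)
    v[i] <- sample(0:2, 6, replace = TRUE)
    v
  }
  g <- gm(
    cbind(base1, jig(base1), jig(base1), jig(base1), base2, jig(base2)),
    marker_ids = sprintf("m%d", 1:6)
  )
  map <- tibble::tibble(
    marker_id = sprintf("m%d", 1:6),
    linkage_group = c(rep("LG1", 4), "LG2", "LG2"),
    position = c(0, 2, 4, 6, 0, 3)
  )
  expect_warning(
    cross_validate(g, map, k = 2, seed = 5, min_complete = 5),
    "< 2 anchors"
  )
})

test_that("the sweep matches cross-validation and is monotone", {
  sim <- small_sim()
  sw <- suppressWarnings(threshold_sweep(
    sim$genotypes, sim$truth_map, c(0.05, 0.1, 0.2, 0.4), k = 4, seed = 9
  ))
  expect_identical(nrow(sw), 4L)
  expect_true(all(diff(sw$mean_efficiency) <= 1e-9))

  # a single-threshold sweep reproduces the cross_validate aggregate
  sw1 <- suppressWarnings(threshold_sweep(
    sim$genotypes, sim$truth_map, 0.1, k = 4, seed = 9
  ))
  cv <- suppressWarnings(cross_validate(
    sim$genotypes, sim$truth_map, k = 4, threshold = 0.1, seed = 9
  ))
  expect_equal(sw1$mean_efficiency, cv$aggregate$efficiency_mean)
  expect_equal(sw1$mean_accuracy, cv$aggregate$accuracy_mean)

  expect_error(
    threshold_sweep(
      sim$genotypes, sim$truth_map, c(0.2, 0.1), k = 4, seed = 9
    ),
    "ascending"
  )
})
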