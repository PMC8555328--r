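profile_of <- function(ids, r2) tibble::tibble(anchor_id = ids, r2 = r2)

test_that("linkage-group assignment follows the top-two rule", {
  map <- toy_map()
  # both strongest anchors on LG1
  a <- assign_chromosome(
    profile_of(c("a1", "a2", "a3"), c(0.9, 0.8, 0.7)), map,
    threshold = 0.1
  )
  expect_identical(a$status, "placed")
  expect_identical(a$linkage_group, "LG1")
  expect_equal(c(a$top_r2, a$second_r2), c(0.9, 0.8))

  # top two disagree
  d <- assign_chromosome(
    profile_of(c("a1", "a3"), c(0.9, 0.8)), map, threshold = 0.1
  )
  expect_identical(d$status, "unplaced")
  expect_identical(d$reason, "top_two_disagree")

  # nothing clears the strict threshold
  n <- assign_chromosome(
    profile_of(c("a1", "a2"), c(0.09, 0.05)), map, threshold = 0.1
  )
  expect_identical(n$reason, "no_anchor_above_threshold")

  # exactly at the threshold does not count (strict >)
  s <- assign_chromosome(
    profile_of(c("a1", "a2"), c(0.5, 0.1)), map, threshold = 0.1
  )
  expect_identical(s$reason, "single_anchor_only")

  expect_error(
    assign_chromosome(profile_of("zz", 0.9), map), "absent from map"
  )
})

test_that("second-slot ties prefer agreement, then smallest id", {
  map <- toy_map()
  tie <- assign_chromosome(
    profile_of(c("a1", "a2", "a3"), c(0.9, 0.6, 0.6)), map, threshold = 0.1
  )
  expect_identical(tie$status, "placed")
  expect_identical(tie$linkage_group, "LG1")

  tie2 <- assign_chromosome(
    profile_of(c("a1", "a3", "a4"), c(0.9, 0.6, 0.6)), map, threshold = 0.1
  )
  expect_identical(tie2$reason, "top_two_disagree")
})

test_that("position estimation is the r2-weighted anchor mean", {
  map <- toy_map()
  # (0.3 * 0 + 0.1 * 10) / 0.4 = 2.5 on LG1's anchors at 0 and 10 cM
  e <- estimate_position(
    profile_of(c("a1", "a2"), c(0.3, 0.1)), map, "LG1", threshold = 0.05
  )
  expect_equal(e$position, 2.5)
  expect_identical(e$n_anchors_used, 2L)

  # equal weights: plain mean
  e2 <- estimate_position(
    profile_of(c("a1", "a2"), c(0.4, 0.4)), map, "LG1", threshold = 0.1
  )
  expect_equal(e2$position, 5)

  # hand-checked weighted mean with anchors at 10 and 20 cM
  map2 <- tibble::tibble(
    marker_id = c("b1", "b2"), linkage_group = "LG9", position = c(10, 20)
  )
  e3 <- estimate_position(
    profile_of(c("b1", "b2"), c(0.3, 0.1)), map2, "LG9", threshold = 0.05
  )
  expect_equal(e3$position, 12.5)

  # anchors at the same position collapse to it
  map3 <- tibble::tibble(
    marker_id = c("c1", "c2"), linkage_group = "LGx", position = c(7, 7)
  )
  e4 <- estimate_position(
    profile_of(c("c1", "c2"), c(0.9, 0.2)), map3, "LGx", threshold = 0.1
  )
  expect_equal(e4$position, 7)
})

test_that("a duplicate of an anchor places on that anchor's group", {
  set.seed(21)
  n <- 200
  base <- rbinom(n, 2, 0.5)
  flip <- function(v, k) {
    i <- sample(n, k)
    v[i] <- 2 - v[i]
    v
  }
  g <- gm(
    cbind(base, flip(base, 15), rbinom(n, 2, 0.5), base),
    marker_ids = c("a1", "a2", "a3", "cand")
  )
  map <- tibble::tibble(
    marker_id = c("a1", "a2", "a3"),
    linkage_group = c("LG1", "LG1", "LG2"),
    position = c(4, 8, 50)
  )
  pl <- place_markers(g, map, "cand", threshold = 0.1)
  expect_identical(pl$status, "placed")
  expect_identical(pl$linkage_group, "LG1")
  expect_equal(pl$top_r2, 1)
  expect_gte(pl$position, 4)
  expect_lte(pl$position, 8)
})

test_that("candidates failing the MAF gate are reported, not placed", {
  set.seed(5)
  n <- 60
  base <- rbinom(n, 2, 0.5)
  g <- gm(
    cbind(base, base, rep(0L, n)),
    marker_ids = c("a1", "a2", "mono")
  )
  map <- tibble::tibble(
    marker_id = c("a1", "a2"), linkage_group = "LG1", position = c(0, 1)
  )
  pl <- place_markers(g, map, "mono", threshold = 0.1)
  expect_identical(pl$status, "unplaced")
  expect_identical(pl$reason, "undefined_ld")
  expect_identical(pl$note, "monomorphic")
})

test_that("empty candidate sets and overlaps are handled", {
  sim <- small_sim()
  msk <- mask_map(sim$truth_map, fraction = 0.2, seed = 3)
  expect_identical(
    nrow(place_markers(sim$genotypes, msk$anchor_map, character())), 0L
  )
  expect_error(
    place_markers(
      sim$genotypes, msk$anchor_map, msk$anchor_map$marker_id[1]
    ),
    "already on the map"
  )
})

# Brute-force reference: enumerate anchors with scalar r2 calls and redo the
# two-step rule from scratch (independent of the package's internals).
brute_place <- function(g, map, id, threshold, min_complete = 10) {
  r2s <- vapply(
    map$marker_id,
    function(a) pairwise_r2(g[, id], g[, a], min_complete),
    numeric(1)
  )
  df <- data.frame(
    anchor = map$marker_id, lg = map$linkage_group, pos = map$position,
    r2 = unname(r2s), stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$r2) & df$r2 > threshold, ]
  if (nrow(df) < 2) return(list(status = "unplaced"))
  df <- df[order(-df$r2, df$anchor), ]
  top <- df[1, ]
  rest <- df[-1, ]
  tied <- rest[rest$r2 == max(rest$r2), ]
  second <- if (any(tied$lg == top$lg)) {
    tied[tied$lg == top$lg, ][1, ]
  } else {
    tied[1, ]
  }
  if (second$lg != top$lg) return(list(status = "unplaced"))
  on_lg <- df[df$lg == top$lg, ]
  list(
    status = "placed", lg = top$lg,
    pos = sum(on_lg$r2 * on_lg$pos) / sum(on_lg$r2)
  )
}

test_that("placement matches a brute-force reference on small maps", {
  sim <- small_sim()
  g <- sim$genotypes
  anchors <- sim$truth_map[c(1:10, 45:54), ] # <= 20 anchors, both LGs
  cand <- setdiff(colnames(g), anchors$marker_id)[seq(1, 60, by = 7)]
  pl <- place_markers(g, anchors, cand, threshold = 0.1, maf_min = 0)
  for (i in seq_along(cand)) {
    ref <- brute_place(g, anchors, cand[i], threshold = 0.1)
    expect_identical(pl$status[i], ref$status)
    if (ref$status == "placed") {
      expect_identical(pl$linkage_group[i], ref$lg)
      expect_equal(pl$position[i], ref$pos, tolerance = 1e-10)
    }
  }
})

test_that("placed positions are convex and runs are deterministic", {
  sim <- small_sim()
  msk <- mask_map(sim$truth_map, fraction = 0.15, seed = 2)
  p1 <- place_markers(
    sim$genotypes, msk$anchor_map, msk$masked_truth$marker_id
  )
  p2 <- place_markers(
    sim$genotypes, msk$anchor_map, msk$masked_truth$marker_id
  )
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  placed <- p1[p1$status == "placed", ]
  for (i in seq_len(nrow(placed))) {
    prof <- ld_profile(
      sim$genotypes, placed$marker_id[i], msk$anchor_map$marker_id
    )
    contrib <- prof |>
      dplyr::left_join(
        msk$anchor_map, by = c(anchor_id = "marker_id")
      ) |>
      dplyr::filter(
        linkage_group == placed$linkage_group[i], r2 > 0.1
      )
    expect_gte(placed$position[i], min(contrib$position))
    expect_lte(placed$position[i], max(contrib$position))
    expect_identical(placed$n_anchors_used[i], nrow(contrib))
  }
})

test_that("raising the threshold only shrinks the placed set", {
  sim <- small_sim()
  msk <- mask_map(sim$truth_map, fraction = 0.2, seed = 4)
  cand <- msk$masked_truth$marker_id
  placed_at <- function(th) {
    pl <- place_markers(sim$genotypes, msk$anchor_map, cand, threshold = th)
    pl$marker_id[pl$status == "placed"]
  }
  sets <- lapply(c(0.05, 0.1, 0.2, 0.3), placed_at)
  for (i in 2:length(sets)) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})
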