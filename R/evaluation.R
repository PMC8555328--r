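#' Partition mapped markers into random folds
#'
#' Splits the mapped marker ids into `k` disjoint, exhaustive subsets whose
#' sizes differ by at most one, reproducibly for a given seed.
#'
#' @param mapped_ids Character vector of mapped marker ids (unique).
#' @param k Number of folds (`>= 2`, at most the number of ids).
#' @param seed Integer seed for the fold assignment.
#' @return A tibble with columns `marker_id` and `fold` (1..k).
#' @export
make_folds <- function(mapped_ids, k, seed) {
  mapped_ids <- as.character(mapped_ids)
  if (anyDuplicated(mapped_ids)) abort("mapped ids must be unique")
  n <- length(mapped_ids)
  if (k < 2) abort("k must be at least 2")
  if (k > n) abort("k must not exceed the number of mapped markers")
  shuffled <- withr::with_seed(seed, sample(mapped_ids))
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  tibble(marker_id = shuffled, fold = rep(seq_len(k), times = sizes))
}

# Score one fold: placements of the masked markers against their truth.
# Accuracy is over placed markers only; the distance and correlation
# metrics are over placed-and-correct markers (a cM difference across
# different chromosomes is meaningless). Wrong-chromosome placements still
# count against accuracy.
score_fold <- function(placements, truth) {
  j <- placements |>
    left_join(
      truth |> rename(true_lg = "linkage_group", true_pos = "position"),
      by = "marker_id"
    )
  n_masked <- nrow(truth)
  placed <- j$status == "placed"
  n_placed <- sum(placed)
  correct <- placed & j$linkage_group == j$true_lg
  n_correct <- sum(correct, na.rm = TRUE)
  errs <- abs(j$position - j$true_pos)[which(correct)]
  tibble(
    n_masked = n_masked,
    n_placed = n_placed,
    n_correct = n_correct,
    efficiency = 100 * n_placed / n_masked,
    accuracy = if (n_placed > 0) 100 * n_correct / n_placed else NA_real_,
    mean_abs_distance = if (n_correct > 0) mean(errs) else NA_real_,
    sd_abs_distance = if (n_correct > 1) sd(errs) else NA_real_,
    pearson_r = if (n_correct > 1) {
      cor(j$true_pos[which(correct)], j$position[which(correct)])
    } else {
      NA_real_
    }
  )
}

cv_metric_cols <- c(
  "efficiency", "accuracy", "mean_abs_distance", "sd_abs_distance",
  "pearson_r"
)

aggregate_folds <- function(per_fold) {
  per_fold |>
    summarise(dplyr::across(
      dplyr::all_of(cv_metric_cols),
      list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd(.x, na.rm = TRUE))
    ))
}

# Warn (once per fold) about linkage groups left too thin to anchor.
check_fold_anchors <- function(anchor_map, fold) {
  sizes <- table(anchor_map$linkage_group)
  thin <- names(sizes)[sizes < 2]
  if (length(thin)) {
    warn(sprintf(
      "fold %d leaves linkage group(s) with < 2 anchors: %s",
      fold, toString(thin)
    ))
  }
}

#' Masking cross-validation of LD-based placement
#'
#' The mapped markers are partitioned into `k` random folds; each fold in
#' turn is masked (treated as unmapped), placed against the reduced map,
#' and scored against its known positions. Per-fold metrics: efficiency
#' (% of masked markers placed on any linkage group), accuracy (% of placed
#' markers on the correct linkage group), precision (mean and SD of the
#' absolute cM difference between known and estimated positions over
#' correctly assigned markers) and the Pearson correlation of known vs
#' estimated cM positions over the same markers. The aggregate is the
#' unweighted mean (and SD) over folds.
#'
#' @param g A genotype matrix holding all mapped markers.
#' @param map The full genetic map (ground truth).
#' @param k Number of folds. Default 20.
#' @param threshold r^2 threshold (strict `>`). Default 0.1.
#' @param seed Integer seed for the fold partition (required).
#' @param maf_min,min_complete Passed to [place_markers()].
#' @return An object of class `lode_cv`: list with `per_fold` (tibble, one
#'   row per fold), `aggregate` (one row of means and SDs), `folds`, and
#'   the parameters. [tidy()] returns `per_fold`; [glance()] the aggregate.
#' @export
cross_validate <- function(g, map, k = 20, threshold = 0.1, seed,
                           maf_min = 0.01, min_complete = 10) {
  g <- validate_genotypes(g)
  map <- validate_map(map)
  if (missing(seed)) abort("seed is required for the fold partition")
  folds <- make_folds(map$marker_id, k, seed)
  per_fold <- purrr::map(seq_len(k), function(f) {
    masked <- folds$marker_id[folds$fold == f]
    anchor_map <- filter(map, !.data$marker_id %in% masked)
    check_fold_anchors(anchor_map, f)
    pl <- place_markers(g, anchor_map, masked,
      threshold = threshold, maf_min = maf_min, min_complete = min_complete
    )
    truth <- filter(map, .data$marker_id %in% masked)
    mutate(score_fold(pl, truth), fold = f, .before = 1)
  }) |>
    list_rbind()
  structure(
    list(
      per_fold = per_fold,
      aggregate = aggregate_folds(per_fold),
      folds = folds,
      k = k, threshold = threshold, seed = seed,
      maf_min = maf_min, min_complete = min_complete
    ),
    class = "lode_cv"
  )
}

#' @export
print.lode_cv <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "%d-fold masking cross-validation (threshold r2 > %g, seed %d)\n",
    x$k, x$threshold, x$seed
  ))
  cat(sprintf(
    "  efficiency %.2f%% (sd %.2f), accuracy %.2f%% (sd %.2f)\n",
    a$efficiency_mean, a$efficiency_sd, a$accuracy_mean, a$accuracy_sd
  ))
  cat(sprintf(
    "  |known - estimated| %.2f cM (sd of fold means %.2f), Pearson r %.3f\n",
    a$mean_abs_distance_mean, a$mean_abs_distance_sd, a$pearson_r_mean
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lode_cv <- function(x, ...) x$per_fold

#' @exportS3Method generics::glance
glance.lode_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(k = x$k, threshold = x$threshold, seed = x$seed),
    x$aggregate
  )
}

#' Sweep the r^2 threshold in cross-validation
#'
#' Re-runs the masking cross-validation over a grid of r^2 thresholds while
#' holding the fold partition fixed (same seed), so the comparison isolates
#' the threshold effect. Because raising the threshold can only shrink the
#' supra-threshold anchor set, per-fold efficiency is non-increasing in the
#' threshold.
#'
#' @inheritParams cross_validate
#' @param thresholds Ascending vector of r^2 thresholds, e.g.
#'   `c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)`.
#' @return A `lode_sweep` tibble with one row per threshold: `threshold`,
#'   `mean_efficiency`, `mean_accuracy`, `sd_efficiency`, `sd_accuracy`.
#' @export
threshold_sweep <- function(g, map, thresholds, k = 20, seed,
                            maf_min = 0.01, min_complete = 10) {
  g <- validate_genotypes(g)
  map <- validate_map(map)
  if (missing(seed)) abort("seed is required for the fold partition")
  if (length(thresholds) < 1 || is.unsorted(thresholds)) {
    abort("thresholds must be a non-empty ascending vector")
  }
  folds <- make_folds(map$marker_id, k, seed)
  # Precompute per-fold r^2 matrices once; thresholding them is cheap.
  prep <- purrr::map(seq_len(k), function(f) {
    masked <- folds$marker_id[folds$fold == f]
    anchor_map <- filter(map, !.data$marker_id %in% masked)
    check_fold_anchors(anchor_map, f)
    st <- marker_stats(g[, masked, drop = FALSE])
    maf_fail_note <- ifelse(
      st$monomorphic, "monomorphic",
      ifelse(st$maf <= maf_min, "maf_at_or_below_minimum", NA_character_)
    )
    r2m <- r2_cross(
      g[, masked, drop = FALSE],
      g[, anchor_map$marker_id, drop = FALSE],
      min_complete = min_complete
    )$r2
    list(
      masked = masked, anchor_map = anchor_map, r2m = r2m,
      maf_fail_note = maf_fail_note,
      truth = filter(map, .data$marker_id %in% masked)
    )
  })
  rows <- purrr::map(thresholds, function(th) {
    per_fold <- purrr::map(prep, function(p) {
      pl <- placements_from_r2(p$masked, p$r2m, p$anchor_map, th,
        maf_fail_note = p$maf_fail_note
      )
      score_fold(pl, p$truth)
    }) |>
      list_rbind()
    tibble(
      threshold = th,
      mean_efficiency = mean(per_fold$efficiency, na.rm = TRUE),
      mean_accuracy = mean(per_fold$accuracy, na.rm = TRUE),
      sd_efficiency = sd(per_fold$efficiency, na.rm = TRUE),
      sd_accuracy = sd(per_fold$accuracy, na.rm = TRUE)
    )
  })
  out <- list_rbind(rows)
  class(out) <- c("lode_sweep", class(out))
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  out
}

#' @exportS3Method generics::tidy
tidy.lode_sweep <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "lode_sweep")
  out
}
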