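# Pairwise-complete r^2 between every column of X and every column of Y.
#
# Computed from sums over per-pair complete observations:
#   r^2 = cov^2 / (var_x * var_y), all three restricted to samples where
#   both calls are non-missing. Done with five crossprods so the per-pair
#   complete count is available (stats::cor does not expose it) and so a
#   zero-variance subset yields a clean per-pair NA rather than a warning.
# Entries with fewer than min_complete complete pairs, or zero variance in
# either restricted vector, are NA.
r2_cross <- function(X, Y, min_complete = 10) {
  Mx <- !is.na(X)
  My <- !is.na(Y)
  X0 <- X
  X0[!Mx] <- 0
  Y0 <- Y
  Y0[!My] <- 0
  storage.mode(X0) <- "double"
  storage.mode(Y0) <- "double"
  n <- crossprod(Mx, My)
  sx <- crossprod(X0, My)
  sy <- crossprod(Mx, Y0)
  sxy <- crossprod(X0, Y0)
  sxx <- crossprod(X0 * X0, My)
  syy <- crossprod(Mx, Y0 * Y0)
  ok <- n >= max(2, min_complete)
  covxy <- sxy - sx * sy / ifelse(n > 0, n, 1)
  vx <- sxx - sx * sx / ifelse(n > 0, n, 1)
  vy <- syy - sy * sy / ifelse(n > 0, n, 1)
  defined <- ok & vx > 1e-9 & vy > 1e-9
  r2 <- matrix(NA_real_, nrow(n), ncol(n), dimnames = dimnames(n))
  r2[defined] <- pmin(1, (covxy[defined]^2) / (vx[defined] * vy[defined]))
  list(r2 = r2, n_complete = n)
}

#' Pairwise r^2 between two genotype vectors
#'
#' The linkage-disequilibrium statistic used throughout: the squared
#' Pearson correlation of two markers' 0/1/2 genotype allele counts,
#' computed without phasing. Samples with a missing call in either vector
#' are excluded pair-wise. The estimate is undefined (`NA`) when fewer than
#' `min_complete` complete pairs remain or when either restricted vector
#' has zero variance.
#'
#' @param x,y Numeric vectors of equal length with values in
#'   `{0, 1, 2, NA}`.
#' @param min_complete Minimum number of samples with both calls
#'   non-missing for the estimate to be defined; low counts give spuriously
#'   high r^2. Default 10.
#' @return A single value in `[0, 1]`, or `NA` when undefined.
#' @export
pairwise_r2 <- function(x, y, min_complete = 10) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least two samples")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < max(2, min_complete)) return(NA_real_)
  x <- x[ok]
  y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  min(1, cor(x, y)^2)
}

#' LD profile of one target marker against mapped anchors
#'
#' Computes r^2 between `target_id` and every marker in `mapped_ids`.
#' Undefined pairs (too few complete observations or zero variance) are
#' omitted from the rows but counted in the `n_undefined` attribute.
#'
#' @param g A genotype matrix containing target and anchors.
#' @param target_id The unmapped marker of interest.
#' @param mapped_ids Character vector of anchor marker ids (must not
#'   contain `target_id`).
#' @param min_complete Passed to the r^2 estimator; see [pairwise_r2()].
#' @return A tibble with columns `anchor_id`, `r2`, `n_complete` and
#'   attributes `target_id` and `n_undefined`.
#' @export
ld_profile <- function(g, target_id, mapped_ids, min_complete = 10) {
  g <- validate_genotypes(g)
  unknown <- setdiff(c(target_id, mapped_ids), colnames(g))
  if (length(unknown)) {
    abort(paste0("marker id(s) not in genotypes: ", toString(head(unknown, 5))))
  }
  if (target_id %in% mapped_ids) {
    abort("target_id must not be one of the mapped anchors")
  }
  mapped_ids <- unique(mapped_ids)
  res <- r2_cross(g[, target_id, drop = FALSE], g[, mapped_ids, drop = FALSE],
                  min_complete = min_complete)
  r2 <- as.vector(res$r2)
  out <- tibble(
    anchor_id = mapped_ids,
    r2 = r2,
    n_complete = as.integer(res$n_complete[1, ])
  )
  defined <- !is.na(out$r2)
  out <- out[defined, ]
  attr(out, "target_id") <- target_id
  attr(out, "n_undefined") <- sum(!defined)
  out
}

#' Intra-chromosomal marker pairs with distance and r^2
#'
#' Every unordered pair of mapped markers on the same linkage group whose
#' map distance is at most `max_distance` (pairs further apart carry
#' essentially no linkage signal and are conventionally excluded from decay
#' plots) and whose r^2 is defined.
#'
#' @param g A genotype matrix containing all mapped markers.
#' @param map A genetic map tibble.
#' @param max_distance Maximum pair distance in cM. Default 100.
#' @param min_complete See [pairwise_r2()].
#' @return A tibble with columns `linkage_group`, `id1`, `id2`, `distance`
#'   (cM) and `r2`.
#' @export
intra_chromosomal_pairs <- function(g, map, max_distance = 100,
                                    min_complete = 10) {
  g <- validate_genotypes(g)
  map <- validate_map(map)
  missing_ids <- setdiff(map$marker_id, colnames(g))
  if (length(missing_ids)) {
    abort(paste0(
      "map marker(s) absent from genotypes: ", toString(head(missing_ids, 5))
    ))
  }
  by_lg <- split(map, map$linkage_group)
  rows <- purrr::map(by_lg, function(sub) {
    if (nrow(sub) < 2) return(NULL)
    ids <- sub$marker_id
    pos <- sub$position
    res <- r2_cross(g[, ids, drop = FALSE], g[, ids, drop = FALSE],
                    min_complete = min_complete)
    d <- abs(outer(pos, pos, "-"))
    keep <- upper.tri(d) & d <= max_distance & !is.na(res$r2)
    if (!any(keep)) return(NULL)
    idx <- which(keep, arr.ind = TRUE)
    tibble(
      linkage_group = sub$linkage_group[1],
      id1 = ids[idx[, 1]],
      id2 = ids[idx[, 2]],
      distance = d[keep],
      r2 = res$r2[keep]
    )
  })
  out <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(
      linkage_group = character(), id1 = character(), id2 = character(),
      distance = double(), r2 = double()
    ))
  }
  out
}

#' LD decay over genetic distance
#'
#' Smooths pairwise r^2 against map distance and locates the decay
#' distance: the smallest distance at which the smoothed curve has fallen
#' to the threshold. Also reports the empirical percentile of the threshold
#' within the observed r^2 values (e.g. a threshold sitting at the 75th
#' percentile means 75% of pairs fall below it).
#'
#' @param pairs A tibble with columns `distance` and `r2`, e.g. from
#'   [intra_chromosomal_pairs()]. At least 20 pairs are required.
#' @param threshold r^2 threshold defining the decay distance. Default 0.1,
#'   the conventional floor for a meaningful pairwise association.
#' @param smoother `"loess"` (default) for a LOESS fit of r^2 on distance,
#'   or `"bin"` for mean r^2 in fixed-width distance bins.
#' @param span LOESS span. Default 0.5.
#' @param bin_width Bin width in cM for the binned smoother. Default 1.
#' @param n_grid Number of grid points at which the LOESS curve is
#'   evaluated. Default 256.
#' @return An object of class `ld_decay` with elements `pairs`, `smooth`
#'   (tibble of `distance`, `r2`), `decay_distance` (cM; `NA` when the
#'   curve never reaches the threshold), `crossed`, `threshold`,
#'   `percentile_of_threshold` and the smoother settings.
#' @export
ld_decay <- function(pairs, threshold = 0.1, smoother = c("loess", "bin"),
                     span = 0.5, bin_width = 1, n_grid = 256) {
  smoother <- match.arg(smoother)
  pairs <- as_tibble(pairs)
  if (!all(c("distance", "r2") %in% names(pairs))) {
    abort("pairs needs columns distance and r2")
  }
  pairs <- filter(pairs, !is.na(.data$r2), is.finite(.data$distance))
  if (nrow(pairs) < 20) {
    abort("need at least 20 defined pairs to estimate LD decay")
  }
  if (smoother == "loess") {
    fit <- loess(r2 ~ distance, data = pairs, span = span, degree = 2)
    grid <- seq(min(pairs$distance), max(pairs$distance), length.out = n_grid)
    sm <- as.vector(predict(fit, newdata = data.frame(distance = grid)))
  } else {
    brk <- seq(
      floor(min(pairs$distance)),
      max(pairs$distance) + bin_width, by = bin_width
    )
    bin <- cut(pairs$distance, breaks = brk, include.lowest = TRUE)
    sm_tab <- tapply(pairs$r2, bin, mean)
    mids <- (brk[-length(brk)] + brk[-1]) / 2
    keep <- !is.na(sm_tab)
    grid <- mids[keep]
    sm <- as.vector(sm_tab[keep])
  }
  below <- which(!is.na(sm) & sm <= threshold)
  crossed <- length(below) > 0
  structure(
    list(
      pairs = pairs,
      smooth = tibble(distance = grid, r2 = sm),
      decay_distance = if (crossed) grid[below[1]] else NA_real_,
      crossed = crossed,
      threshold = threshold,
      percentile_of_threshold = 100 * ecdf(pairs$r2)(threshold),
      smoother = smoother,
      span = span,
      bin_width = bin_width
    ),
    class = "ld_decay"
  )
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay profile (", nrow(x$pairs), " pairs, ", x$smoother,
    " smoother)\n",
    sep = ""
  )
  if (x$crossed) {
    cat(sprintf(
      "  decay distance at r2 = %g: %.2f cM\n", x$threshold, x$decay_distance
    ))
  } else {
    cat(sprintf(
      "  smoothed curve never falls to r2 = %g within the observed range\n",
      x$threshold
    ))
  }
  cat(sprintf(
    "  threshold sits at the %.1fth percentile of observed r2\n",
    x$percentile_of_threshold
  ))
  invisible(x)
}
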