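# Reasons a candidate can fail placement.
UNPLACED_REASONS <- c(
  "no_anchor_above_threshold", "single_anchor_only",
  "top_two_disagree", "undefined_ld"
)

# Core of the linkage-group assignment rule, on a pre-joined profile
# (anchor_id, r2, linkage_group, position; defined r2 only).
# Tie-break at the second-highest slot: prefer an anchor agreeing with the
# top anchor's linkage group, then the lexicographically smallest id.
assign_core <- function(prof, threshold) {
  sup <- prof[prof$r2 > threshold, , drop = FALSE]
  if (nrow(sup) == 0) {
    return(list(
      status = "unplaced", reason = "no_anchor_above_threshold",
      linkage_group = NA_character_,
      top_r2 = if (nrow(prof)) max(prof$r2) else NA_real_,
      second_r2 = NA_real_
    ))
  }
  if (nrow(sup) == 1) {
    return(list(
      status = "unplaced", reason = "single_anchor_only",
      linkage_group = NA_character_,
      top_r2 = sup$r2[1], second_r2 = NA_real_
    ))
  }
  ord <- order(-sup$r2, sup$anchor_id)
  top <- sup[ord[1], ]
  rest <- sup[ord[-1], , drop = FALSE]
  second_r2 <- rest$r2[1]
  cand <- rest[rest$r2 == second_r2, , drop = FALSE]
  agree <- cand[cand$linkage_group == top$linkage_group, , drop = FALSE]
  second <- if (nrow(agree)) agree[1, ] else cand[1, ]
  if (identical(second$linkage_group, top$linkage_group)) {
    list(
      status = "placed", reason = NA_character_,
      linkage_group = top$linkage_group,
      top_r2 = top$r2, second_r2 = second$r2
    )
  } else {
    list(
      status = "unplaced", reason = "top_two_disagree",
      linkage_group = NA_character_,
      top_r2 = top$r2, second_r2 = second$r2
    )
  }
}

# r^2-weighted mean position over all supra-threshold anchors on lg.
estimate_core <- function(prof, lg, threshold) {
  A <- prof[prof$linkage_group == lg & prof$r2 > threshold, , drop = FALSE]
  if (nrow(A) == 0) {
    abort("no anchors above the threshold on the assigned linkage group")
  }
  list(
    position = weighted.mean(A$position, w = A$r2),
    n_anchors_used = nrow(A)
  )
}

join_profile <- function(profile, map) {
  profile <- as_tibble(profile)
  map <- validate_map(map)
  missing_ids <- setdiff(profile$anchor_id, map$marker_id)
  if (length(missing_ids)) {
    abort(paste0(
      "profile anchor(s) absent from map: ", toString(head(missing_ids, 5))
    ))
  }
  profile |>
    left_join(map, by = c(anchor_id = "marker_id")) |>
    filter(!is.na(.data$r2))
}

#' Assign an unmapped marker to a linkage group
#'
#' Step one of the placement algorithm: among mapped anchors with r^2
#' strictly above the threshold, take the two with the highest r^2. If both
#' lie on the same linkage group the marker is assigned there; otherwise it
#' is left unplaced with a reason (`no_anchor_above_threshold`,
#' `single_anchor_only`, or `top_two_disagree`). Ties at the second-highest
#' r^2 are broken deterministically: anchors agreeing with the top anchor's
#' linkage group first, then the lexicographically smallest marker id.
#'
#' @param profile An LD profile tibble from [ld_profile()].
#' @param map The anchor genetic map.
#' @param threshold r^2 threshold (strict `>`). Default 0.1.
#' @return A list with `status`, `linkage_group`, `top_r2`, `second_r2`,
#'   `reason`.
#' @export
assign_chromosome <- function(profile, map, threshold = 0.1) {
  assign_core(join_profile(profile, map), threshold)
}

#' Estimate a marker's position within its assigned linkage group
#'
#' Step two of the placement algorithm: the r^2-weighted average of the
#' positions of all anchors on the assigned linkage group whose r^2 is
#' strictly above the threshold (multi-point: every supra-threshold anchor
#' contributes, not just the top two).
#'
#' @inheritParams assign_chromosome
#' @param linkage_group The group returned by [assign_chromosome()].
#' @return A list with `position` (cM) and `n_anchors_used`.
#' @export
estimate_position <- function(profile, map, linkage_group, threshold = 0.1) {
  estimate_core(join_profile(profile, map), linkage_group, threshold)
}

unplaced_row <- function(id, reason, note = NA_character_,
                         top_r2 = NA_real_, second_r2 = NA_real_) {
  tibble(
    marker_id = id, status = "unplaced", linkage_group = NA_character_,
    position = NA_real_, top_r2 = top_r2, second_r2 = second_r2,
    n_anchors_used = NA_integer_, reason = reason, note = note
  )
}

# Place one candidate from its row of the r^2 matrix against the anchors.
place_one <- function(id, r2row, anchor_map, threshold) {
  defined <- !is.na(r2row)
  if (!any(defined)) {
    return(unplaced_row(id, "undefined_ld", note = "all_ld_undefined"))
  }
  prof <- tibble(
    anchor_id = anchor_map$marker_id[defined],
    r2 = unname(r2row[defined]),
    linkage_group = anchor_map$linkage_group[defined],
    position = anchor_map$position[defined]
  )
  a <- assign_core(prof, threshold)
  if (a$status != "placed") {
    return(unplaced_row(id, a$reason,
      top_r2 = a$top_r2, second_r2 = a$second_r2
    ))
  }
  e <- estimate_core(prof, a$linkage_group, threshold)
  tibble(
    marker_id = id, status = "placed", linkage_group = a$linkage_group,
    position = e$position, top_r2 = a$top_r2, second_r2 = a$second_r2,
    n_anchors_used = as.integer(e$n_anchors_used), reason = NA_character_,
    note = NA_character_
  )
}

# Shared by place_markers() and threshold_sweep(): candidates whose MAF
# check failed are unplaced(undefined_ld); the rest run the two-step rule.
placements_from_r2 <- function(candidate_ids, r2m, anchor_map, threshold,
                               maf_fail_note) {
  if (length(candidate_ids) == 0) {
    out <- unplaced_row(character(), character(), character())
    class(out) <- c("lode_placements", class(out))
    attr(out, "threshold") <- threshold
    return(out)
  }
  rows <- map(seq_along(candidate_ids), function(i) {
    id <- candidate_ids[i]
    if (!is.na(maf_fail_note[i])) {
      return(unplaced_row(id, "undefined_ld", note = maf_fail_note[i]))
    }
    place_one(id, r2m[i, ], anchor_map, threshold)
  })
  out <- list_rbind(rows)
  class(out) <- c("lode_placements", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Place unmapped markers on a genetic map
#'
#' Runs the full two-step LD placement for a set of candidate markers:
#' candidates failing the MAF filter are reported unplaced with reason
#' `undefined_ld`; the others are profiled against all mapped anchors,
#' assigned a linkage group from the two strongest supra-threshold
#' associations ([assign_chromosome()]) and positioned by the r^2-weighted
#' anchor average ([estimate_position()]). Candidates are placed
#' independently: a newly placed marker never serves as an anchor within
#' the same run, so results do not depend on candidate order.
#'
#' @param g A genotype matrix holding candidates and mapped markers.
#' @param map The anchor genetic map.
#' @param candidate_ids Markers to place; must be disjoint from the map.
#' @param threshold r^2 threshold (strict `>`). Default 0.1.
#' @param maf_min Candidates with MAF at or below this are not attempted.
#'   Default 0.01.
#' @param min_complete Minimum complete pairs per r^2; see [pairwise_r2()].
#' @return A `lode_placements` tibble (one row per candidate, input order)
#'   with columns `marker_id`, `status`, `linkage_group`, `position`,
#'   `top_r2`, `second_r2`, `n_anchors_used`, `reason`, `note`, and a
#'   `summary` attribute counting statuses and reasons. [glance()] returns
#'   the counts as a one-row tibble.
#' @export
place_markers <- function(g, map, candidate_ids, threshold = 0.1,
                          maf_min = 0.01, min_complete = 10) {
  g <- validate_genotypes(g)
  map <- validate_map(map)
  candidate_ids <- as.character(candidate_ids)
  if (anyDuplicated(candidate_ids)) abort("candidate ids must be unique")
  overlap <- intersect(candidate_ids, map$marker_id)
  if (length(overlap)) {
    abort(paste0(
      "candidate(s) already on the map: ", toString(head(overlap, 5))
    ))
  }
  unknown <- setdiff(c(candidate_ids, map$marker_id), colnames(g))
  if (length(unknown)) {
    abort(paste0(
      "marker id(s) absent from genotypes: ", toString(head(unknown, 5))
    ))
  }
  if (length(candidate_ids) == 0) {
    out <- placements_from_r2(character(), NULL, map, threshold, character())
    attr(out, "summary") <- tibble(
      status = character(), reason = character(), n = integer()
    )
    return(out)
  }
  st <- marker_stats(g[, candidate_ids, drop = FALSE])
  maf_fail_note <- ifelse(
    st$monomorphic, "monomorphic",
    ifelse(st$maf <= maf_min, "maf_at_or_below_minimum", NA_character_)
  )
  r2m <- r2_cross(
    g[, candidate_ids, drop = FALSE],
    g[, map$marker_id, drop = FALSE],
    min_complete = min_complete
  )$r2
  out <- placements_from_r2(candidate_ids, r2m, map, threshold, maf_fail_note)
  attr(out, "summary") <- out |>
    count(.data$status, .data$reason, name = "n") |>
    as_tibble()
  out
}

#' @export
print.lode_placements <- function(x, ...) {
  n_placed <- sum(x$status == "placed")
  cat(sprintf(
    "LD placements: %d candidate(s), %d placed (threshold r2 > %g)\n",
    nrow(x), n_placed, attr(x, "threshold") %||% NA
  ))
  NextMethod()
}

#' @exportS3Method generics::glance
glance.lode_placements <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    n_placed = sum(x$status == "placed"),
    n_no_anchor = sum(x$reason %in% "no_anchor_above_threshold"),
    n_single_anchor = sum(x$reason %in% "single_anchor_only"),
    n_top_two_disagree = sum(x$reason %in% "top_two_disagree"),
    n_undefined_ld = sum(x$reason %in% "undefined_ld"),
    threshold = attr(x, "threshold") %||% NA_real_
  )
}

#' @exportS3Method generics::tidy
tidy.lode_placements <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "summary") <- NULL
  out
}
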