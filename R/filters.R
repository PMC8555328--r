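#' Per-marker quality statistics
#'
#' For each marker: minor allele frequency `maf = min(p, 1 - p)` with
#' `p = sum(calls) / (2 * n_non_missing)` (the alternate-allele frequency of
#' the 0/1/2 allele counts), the call rate (fraction of non-missing calls),
#' and a monomorphic flag (all non-missing calls identical). Markers with no
#' non-missing calls get `call_rate = 0`, `maf = 0` and are flagged
#' monomorphic.
#'
#' @param g A genotype matrix (see [validate_genotypes()]).
#' @return A tibble with columns `marker_id`, `maf`, `call_rate`,
#'   `monomorphic`, one row per marker in input order.
#' @export
marker_stats <- function(g) {
  g <- validate_genotypes(g)
  if (nrow(g) < 1) abort("genotype matrix has no samples")
  n <- nrow(g)
  n_obs <- colSums(!is.na(g))
  s <- colSums(g, na.rm = TRUE)
  p <- ifelse(n_obs > 0, s / (2 * n_obs), NA_real_)
  maf <- ifelse(n_obs > 0, pmin(p, 1 - p), 0)
  mx <- suppressWarnings(apply(g, 2, max, na.rm = TRUE))
  mn <- suppressWarnings(apply(g, 2, min, na.rm = TRUE))
  mono <- n_obs == 0 | mx == mn
  tibble(
    marker_id = colnames(g),
    maf = unname(maf),
    call_rate = unname(n_obs / n),
    monomorphic = unname(mono)
  )
}

#' Filter markers on MAF, call rate and polymorphism
#'
#' Keeps markers with `maf > maf_min` (strict inequality, the conventional
#' reading of a "MAF > 0.01" inclusion rule), `call_rate >= call_rate_min`,
#' and at least two observed genotype classes. Monomorphic markers are
#' always dropped: their genotype variance is zero, so r^2 against them is
#' undefined. Marker order is preserved and the operation is idempotent.
#'
#' @param g A genotype matrix.
#' @param maf_min Minimum minor allele frequency in `[0, 0.5]`; markers at
#'   or below it are dropped. Default 0.01.
#' @param call_rate_min Minimum call rate in `[0, 1]`; markers below it are
#'   dropped. Default 0.9.
#' @return A list with `genotypes` (the filtered matrix) and `report`, a
#'   tibble of dropped markers with columns `marker_id` and `reason`
#'   (semicolon-joined when several rules fail).
#' @export
filter_markers <- function(g, maf_min = 0.01, call_rate_min = 0.9) {
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min > 0.5) {
    abort("maf_min must lie in [0, 0.5]")
  }
  if (!is.numeric(call_rate_min) || call_rate_min < 0 || call_rate_min > 1) {
    abort("call_rate_min must lie in [0, 1]")
  }
  g <- validate_genotypes(g)
  st <- marker_stats(g)
  reasons <- purrr::pmap_chr(
    list(st$maf, st$call_rate, st$monomorphic),
    function(maf, cr, mono) {
      r <- c(
        if (mono) "monomorphic",
        if (!mono && maf <= maf_min) "maf_at_or_below_minimum",
        if (cr < call_rate_min) "call_rate_below_minimum"
      )
      if (length(r)) paste(r, collapse = ";") else NA_character_
    }
  )
  keep <- is.na(reasons)
  report <- tibble(marker_id = st$marker_id, reason = reasons) |>
    filter(!is.na(.data$reason))
  list(genotypes = g[, keep, drop = FALSE], report = report)
}
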