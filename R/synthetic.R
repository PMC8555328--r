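#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a per-meiosis
#' recombination fraction, assuming no crossover interference:
#' `c = (1 - exp(-2 d / 100)) / 2`. Zero distance gives zero recombination;
#' large distances approach free recombination (0.5).
#'
#' @param d Distance(s) in cM, non-negative.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane <- function(d) 0.5 * (1 - exp(-2 * d / 100))

#' Simulation configuration
#'
#' Parameters of the forward-in-time breeding-population simulator. The
#' defaults emulate an elite breeding program: a handful of founders and a
#' few generations of random mating, which leaves strong linkage
#' disequilibrium that decays smoothly with map distance — the regime in
#' which LD-based marker placement is expected to work.
#'
#' @param n_linkage_groups Number of chromosomes. Default 3.
#' @param lg_length Length of each linkage group in cM. Default 100.
#' @param n_markers_per_lg Markers per linkage group, positions drawn
#'   uniformly then sorted. Default 200.
#' @param n_founders Number of diploid founder individuals; few founders is
#'   what generates LD. Default 8.
#' @param n_generations Random-mating generations after the founders.
#'   Default 5.
#' @param n_samples Population size of each post-founder generation (and of
#'   the genotyped output). Default 500.
#' @param founder_allele_freq_range Interval from which each marker's
#'   founder alternate-allele frequency is drawn. Default `c(0.1, 0.9)`.
#' @param missing_rate Probability that any one genotype call is set
#'   missing, in `[0, 0.5)`. Default 0.02.
#' @param seed Integer seed; the simulation is bit-reproducible. Default 1.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_linkage_groups = 3, lg_length = 100,
                       n_markers_per_lg = 200, n_founders = 8,
                       n_generations = 5, n_samples = 500,
                       founder_allele_freq_range = c(0.1, 0.9),
                       missing_rate = 0.02, seed = 1) {
  counts <- c(
    n_linkage_groups = n_linkage_groups, n_markers_per_lg = n_markers_per_lg,
    n_founders = n_founders, n_generations = n_generations,
    n_samples = n_samples
  )
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("all counts must be integers >= 1")
  }
  if (lg_length <= 0) abort("lg_length must be positive")
  fr <- founder_allele_freq_range
  if (length(fr) != 2 || fr[1] <= 0 || fr[2] >= 1 || fr[1] > fr[2]) {
    abort("founder_allele_freq_range must lie within (0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 0.5) {
    abort("missing_rate must lie in [0, 0.5)")
  }
  structure(
    list(
      n_linkage_groups = as.integer(n_linkage_groups),
      lg_length = lg_length,
      n_markers_per_lg = as.integer(n_markers_per_lg),
      n_founders = as.integer(n_founders),
      n_generations = as.integer(n_generations),
      n_samples = as.integer(n_samples),
      founder_allele_freq_range = fr,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# One round of meioses: a gamete for each entry of `parents`, recombining
# the parental haplotype pair with crossover probability haldane(gap)
# between adjacent markers, independently per linkage group.
make_gametes <- function(H1, H2, parents, rec_by_lg) {
  n <- length(parents)
  A <- H1[parents, , drop = FALSE]
  B <- H2[parents, , drop = FALSE]
  out <- A
  col <- 0L
  for (r in rec_by_lg) {
    m <- length(r) + 1L
    start <- rbinom(n, 1, 0.5)
    if (m > 1) {
      x <- matrix(rbinom(n * (m - 1L), 1, rep(r, each = n)), n, m - 1L)
      cs <- if (m == 2L) x else t(apply(x, 1, cumsum))
      src <- (start + cbind(0L, cs)) %% 2
    } else {
      src <- matrix(start, n, 1)
    }
    idx <- col + seq_len(m)
    blk <- A[, idx, drop = FALSE]
    sel <- src == 1
    blk[sel] <- B[, idx, drop = FALSE][sel]
    out[, idx] <- blk
    col <- col + m
  }
  out
}

#' Simulate a breeding population with map-distance-dependent LD
#'
#' Forward-in-time simulation: founder haplotypes are drawn per marker from
#' the configured allele-frequency range; each subsequent generation is
#' produced by sampling two parents uniformly with replacement and forming
#' each gamete by a recombination walk along every linkage group, with
#' crossover probability between adjacent markers given by the Haldane map
#' function of their cM gap. The narrow founder base makes the final
#' population a mosaic of few haplotypes, so intra-chromosomal r^2 decays
#' smoothly with map distance while markers on different linkage groups
#' stay essentially uncorrelated. Final diploid genotypes are coded 0/1/2
#' with missing calls injected uniformly at random.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `lode_sim`: list with `genotypes` (genotype
#'   matrix, samples x markers), `truth_map` (genetic map tibble covering
#'   every marker) and `config`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) abort("cfg must come from sim_config()")
  withr::with_seed(cfg$seed, {
    G <- cfg$n_linkage_groups
    m <- cfg$n_markers_per_lg
    lg_names <- sprintf("LG%d", seq_len(G))
    pos_list <- lapply(seq_len(G), function(i) {
      sort(runif(m, 0, cfg$lg_length))
    })
    marker_ids <- unlist(lapply(seq_len(G), function(i) {
      sprintf("%s_m%04d", lg_names[i], seq_len(m))
    }))
    truth_map <- tibble(
      marker_id = marker_ids,
      linkage_group = rep(lg_names, each = m),
      position = unlist(pos_list)
    )
    M <- G * m
    p <- runif(
      M, cfg$founder_allele_freq_range[1], cfg$founder_allele_freq_range[2]
    )
    nf <- cfg$n_founders
    H1 <- matrix(rbinom(nf * M, 1, rep(p, each = nf)), nf, M)
    H2 <- matrix(rbinom(nf * M, 1, rep(p, each = nf)), nf, M)
    rec_by_lg <- lapply(pos_list, function(pp) haldane(diff(pp)))
    for (gen in seq_len(cfg$n_generations)) {
      n_cur <- nrow(H1)
      pa <- sample.int(n_cur, cfg$n_samples, replace = TRUE)
      pb <- sample.int(n_cur, cfg$n_samples, replace = TRUE)
      G1 <- make_gametes(H1, H2, pa, rec_by_lg)
      G2 <- make_gametes(H1, H2, pb, rec_by_lg)
      H1 <- G1
      H2 <- G2
    }
    geno <- H1 + H2
    if (cfg$missing_rate > 0) {
      miss <- matrix(
        rbinom(length(geno), 1, cfg$missing_rate) == 1,
        nrow(geno), ncol(geno)
      )
      geno[miss] <- NA_integer_
    }
    dimnames(geno) <- list(
      sprintf("S%04d", seq_len(nrow(geno))), marker_ids
    )
    structure(
      list(
        genotypes = validate_genotypes(geno),
        truth_map = validate_map(truth_map),
        config = cfg
      ),
      class = "lode_sim"
    )
  })
}

#' @export
print.lode_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    paste0(
      "Simulated breeding population: %d samples x %d markers ",
      "(%d LG x %g cM, %d founders, %d generations, seed %d)\n"
    ),
    nrow(x$genotypes), ncol(x$genotypes), cfg$n_linkage_groups,
    cfg$lg_length, cfg$n_founders, cfg$n_generations, cfg$seed
  ))
  invisible(x)
}

#' Mask part of a genetic map
#'
#' Splits a ground-truth map into an anchor map and a held-out set whose
#' positions are hidden from the placement algorithm and kept for scoring.
#' Either a random fraction (seeded) or an explicit id set can be masked.
#'
#' @param truth A genetic map tibble.
#' @param fraction Fraction of markers to mask, in `(0, 1)`; requires
#'   `seed`. Ignored when `ids` is given.
#' @param ids Explicit marker ids to mask.
#' @param seed Integer seed for the random mask.
#' @return A list with `anchor_map` and `masked_truth`, disjoint and
#'   jointly exhaustive. Masking every marker of some linkage group raises
#'   a warning (those markers can never be assigned back correctly).
#' @export
mask_map <- function(truth, fraction = NULL, ids = NULL, seed = NULL) {
  truth <- validate_map(truth)
  if (is.null(ids)) {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1) {
      abort("fraction must lie in (0, 1) when ids is not given")
    }
    if (is.null(seed)) abort("seed is required for a random mask")
    n_mask <- max(1, round(fraction * nrow(truth)))
    ids <- withr::with_seed(seed, sample(truth$marker_id, n_mask))
  } else {
    missing_ids <- setdiff(ids, truth$marker_id)
    if (length(missing_ids)) {
      abort(paste0(
        "mask id(s) not on the map: ", toString(head(missing_ids, 5))
      ))
    }
  }
  anchor_map <- filter(truth, !.data$marker_id %in% ids)
  masked_truth <- filter(truth, .data$marker_id %in% ids)
  gone <- setdiff(
    unique(truth$linkage_group), unique(anchor_map$linkage_group)
  )
  if (length(gone)) {
    warn(paste0(
      "mask removes every marker of linkage group(s): ", toString(gone)
    ))
  }
  list(anchor_map = anchor_map, masked_truth = masked_truth)
}
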