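# Missing-call spellings accepted in delimited genotype matrices.
# Breeding datasets commonly use any of these; all are emitted as NA.
GENO_MISSING <- c("NA", "N", "-9", "")

#' Validate a genotype matrix
#'
#' A genotype matrix is a base integer matrix of biallelic SNP calls coded
#' 0 (homozygous reference), 1 (heterozygous, including all pseudo-diploid
#' heterozygote classes), 2 (homozygous alternate) or `NA` (missing), with
#' unique sample ids as row names and unique marker ids as column names.
#'
#' @param g A samples x markers matrix with values in `{0, 1, 2, NA}`.
#' @return The validated matrix with integer storage, invisibly usable
#'   downstream.
#' @export
validate_genotypes <- function(g) {
  if (!is.matrix(g)) abort("genotypes must be a samples x markers matrix")
  if (is.null(rownames(g)) || is.null(colnames(g))) {
    abort("genotype matrix must carry sample row names and marker column names")
  }
  dup_s <- unique(rownames(g)[duplicated(rownames(g))])
  if (length(dup_s)) {
    abort(paste0("duplicated sample id(s): ", toString(head(dup_s, 5))))
  }
  dup_m <- unique(colnames(g)[duplicated(colnames(g))])
  if (length(dup_m)) {
    abort(paste0("duplicated marker id(s): ", toString(head(dup_m, 5))))
  }
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0L, 1L, 2L))) {
    abort("genotype calls must be 0, 1, 2 or NA")
  }
  storage.mode(g) <- "integer"
  g
}

#' Read a genotype matrix
#'
#' Two dialects are supported. `"matrix"` is a delimited text table
#' (TSV/CSV autodetected from the extension): header row of marker ids,
#' first column of sample ids, cells in `{0, 1, 2}` with missing calls
#' written as `NA`, `N`, `-9` or an empty cell. `"vcf"` is a standard
#' VCF 4.x whose GT subfields are collapsed pseudo-diploid: all-reference
#' alleles map to 0, all-alternate to 2, any mixed call to 1, and any call
#' containing `.` to missing. Non-biallelic VCF records are skipped with a
#' warning giving their count.
#'
#' @param path Path to the genotype file.
#' @param dialect `"matrix"` (default) or `"vcf"`.
#' @return A validated genotype matrix (see [validate_genotypes()]).
#' @export
read_genotypes <- function(path, dialect = c("matrix", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("genotype file not found: ", path))
  switch(dialect,
    matrix = read_genotypes_matrix(path),
    vcf = read_genotypes_vcf(path)
  )
}

read_genotypes_matrix <- function(path) {
  # check the header ourselves: readr would silently de-duplicate repeated
  # marker ids during name repair
  delim <- delim_for(path)
  head_lines <- readLines(path, n = 100, warn = FALSE)
  header <- head_lines[!startsWith(head_lines, "#")][1]
  if (is.na(header)) abort(paste0("genotype file is empty: ", path))
  hdr_ids <- strsplit(header, delim, fixed = TRUE)[[1]][-1]
  dup_h <- unique(hdr_ids[duplicated(hdr_ids)])
  if (length(dup_h)) {
    abort(paste0("duplicated marker id(s): ", toString(head(dup_h, 5))))
  }
  tab <- readr::read_delim(path,
    delim = delim, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  if (ncol(tab) < 2) {
    abort("genotype matrix needs a sample-id column plus at least one marker column")
  }
  sample_ids <- tab[[1]]
  marker_ids <- names(tab)[-1]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  vals <- raw
  vals[is.na(raw) | raw %in% GENO_MISSING] <- NA_character_
  bad <- !is.na(vals) & !(vals %in% c("0", "1", "2"))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "invalid genotype call '%s' at row %d (sample '%s'), column '%s'",
      raw[ij[1], ij[2]], ij[1], sample_ids[ij[1]], marker_ids[ij[2]]
    ))
  }
  g <- matrix(as.integer(vals),
    nrow = nrow(raw),
    dimnames = list(sample_ids, marker_ids)
  )
  validate_genotypes(g)
}

# collapse one GT string (any ploidy, any phasing separator) to 0/1/2/NA
decode_gt <- function(s) {
  if (is.na(s)) return(NA_integer_)
  al <- strsplit(s, "[/|]")[[1]]
  if (length(al) == 0 || any(al == ".")) return(NA_integer_)
  if (all(al == "0")) 0L else if (all(al == "1")) 2L else 1L
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) abort("VCF contains no variant records")
  multi <- !vcfR::is.biallelic(vcf)
  if (any(multi)) {
    warn(sprintf("skipped %d non-biallelic VCF record(s)", sum(multi)))
    vcf <- vcf[!multi, ]
  }
  if (nrow(vcf@fix) == 0) abort("VCF contains no biallelic records")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  u <- unique(as.vector(gt))
  dec <- vapply(u, decode_gt, integer(1), USE.NAMES = FALSE)
  m <- matrix(dec[match(gt, u)], nrow = nrow(gt), dimnames = dimnames(gt))
  validate_genotypes(t(m))
}

#' Write a genotype matrix as delimited text
#'
#' Inverse of the `"matrix"` dialect of [read_genotypes()]: header of marker
#' ids, first column `sample_id`, missing calls written as `NA`.
#'
#' @param g A genotype matrix.
#' @param path Output path (TSV, or CSV when the extension is `.csv`).
#' @return The path, invisibly.
#' @export
write_genotypes <- function(g, path) {
  g <- validate_genotypes(g)
  df <- as_tibble(as.data.frame(g, check.names = FALSE))
  df <- dplyr::bind_cols(tibble(sample_id = rownames(g)), df)
  if (delim_for(path) == ",") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    write_tsv_atomic(df, path)
  }
  invisible(path)
}

#' Validate a genetic map
#'
#' A genetic map is a tibble with columns `marker_id` (unique), a
#' `linkage_group` label, and `position` in centimorgans (finite,
#' non-negative).
#'
#' @param map A data frame with columns `marker_id`, `linkage_group`,
#'   `position` (a `position_cM` column is accepted and renamed).
#' @param require_pairable Require at least one linkage group holding two or
#'   more markers (anchored placement is vacuous otherwise). Default `FALSE`
#'   so that reduced maps arising mid-analysis can still be represented.
#' @return The map as a validated tibble.
#' @export
validate_map <- function(map, require_pairable = FALSE) {
  map <- as_tibble(map)
  if ("position_cM" %in% names(map) && !"position" %in% names(map)) {
    map <- rename(map, position = "position_cM")
  }
  need <- c("marker_id", "linkage_group", "position")
  if (!all(need %in% names(map))) {
    abort(paste0("genetic map needs columns: ", toString(need)))
  }
  if (nrow(map) == 0) abort("genetic map is empty")
  dup <- unique(map$marker_id[duplicated(map$marker_id)])
  if (length(dup)) {
    abort(paste0("duplicated marker id(s) in map: ", toString(head(dup, 5))))
  }
  if (!is.numeric(map$position) || any(!is.finite(map$position)) ||
      any(map$position < 0)) {
    abort("map positions must be finite, non-negative centimorgans")
  }
  if (require_pairable) {
    sizes <- table(map$linkage_group)
    if (!any(sizes >= 2)) {
      abort("no linkage group holds >= 2 markers; weighted placement is vacuous")
    }
  }
  map[, c("marker_id", "linkage_group", "position")]
}

#' Read a genetic map table
#'
#' Reads a tab- or comma-delimited table (autodetected from the extension)
#' with columns `marker_id`, `linkage_group`, `position_cM`. Extra columns
#' (for example those written by [write_extended_map()]) are ignored; when
#' the canonical names are absent the first three columns are used.
#'
#' @param path Path to the map file.
#' @return A genetic map tibble (`marker_id`, `linkage_group`, `position`).
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) abort(paste0("map file not found: ", path))
  tab <- readr::read_delim(path,
    delim = delim_for(path), comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  if (nrow(tab) == 0) abort(paste0("genetic map file is empty: ", path))
  canon <- c("marker_id", "linkage_group", "position_cM")
  if (all(canon %in% names(tab))) {
    tab <- tab[, canon]
  } else if (ncol(tab) >= 3) {
    tab <- tab[, 1:3]
  } else {
    abort("genetic map file needs columns marker_id, linkage_group, position_cM")
  }
  names(tab) <- c("marker_id", "linkage_group", "position")
  pos <- suppressWarnings(as.numeric(tab$position))
  bad <- which(is.na(pos) | !is.finite(pos) | pos < 0)
  if (length(bad)) {
    abort(sprintf(
      "invalid map position '%s' for marker '%s' (row %d)",
      tab$position[bad[1]], tab$marker_id[bad[1]], bad[1]
    ))
  }
  tab$position <- pos
  validate_map(tab, require_pairable = TRUE)
}

#' Write an extended genetic map
#'
#' Serializes the anchor map plus newly placed markers as a TSV with columns
#' `marker_id`, `linkage_group`, `position_cM`, `source` (`anchor` or
#' `ld_placed`), `top_r2` and `n_anchors`. Anchors come first, then placed
#' markers, each block sorted by linkage group and position. Positions are
#' written with six decimal places so the file round-trips bit-stably
#' through [read_genetic_map()].
#'
#' @param map The anchor genetic map.
#' @param placements A placement tibble from [place_markers()] (rows with
#'   `status == "placed"` are written), or `NULL` for none.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_extended_map <- function(map, placements = NULL, path) {
  map <- validate_map(map)
  anchors <- map |>
    arrange(.data$linkage_group, .data$position, .data$marker_id) |>
    mutate(source = "anchor", top_r2 = NA_real_, n_anchors = NA_integer_)
  placed <- NULL
  if (!is.null(placements) && nrow(placements) > 0) {
    overlap <- intersect(placements$marker_id, map$marker_id)
    if (length(overlap)) {
      abort(paste0(
        "placed marker id(s) already on the map: ", toString(head(overlap, 5))
      ))
    }
    pl <- as_tibble(placements)
    if ("status" %in% names(pl)) pl <- filter(pl, .data$status == "placed")
    if (nrow(pl) > 0) {
      placed <- tibble(
        marker_id = pl$marker_id,
        linkage_group = pl$linkage_group,
        position = pl$position,
        source = "ld_placed",
        top_r2 = pl$top_r2,
        n_anchors = as.integer(pl$n_anchors_used)
      ) |>
        arrange(.data$linkage_group, .data$position, .data$marker_id)
    }
  }
  out <- bind_rows(anchors, placed)
  out$position <- sprintf("%.6f", out$position)
  names(out)[names(out) == "position"] <- "position_cM"
  write_tsv_atomic(out, path)
  invisible(path)
}
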