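#' Assign peak centers to fixed-width genomic bins
#'
#' Tiles each chromosome with bins of `bin_width` bp. With no arm
#' definitions, bins start at coordinate 0 and run rightward. When an arm
#' table is supplied (one centromere-origin per chromosome), bins start at
#' the origin and proceed outward along each arm, mirrored on the p arm:
#' p-arm bin 0 covers `[origin - w, origin)`, q-arm bin 0 covers
#' `[origin, origin + w)`. Bins are half-open, so a center sitting exactly
#' on a boundary belongs to the right-hand bin.
#'
#' @param centers A tibble of peak centers (`chrom`, `center`,
#'   `dataset_id`).
#' @param bin_width Bin size in bp, >= 1; default 400.
#' @param arms Optional arm definitions: a tibble with columns `chrom` and
#'   `origin` (centromere coordinate), or the path of a TSV with those
#'   columns. Chromosomes absent from the table use origin 0.
#' @return The input tibble with added columns `arm` (`"q"` for the
#'   increasing arm, `"p"` for the mirrored one), `bin` (index within arm),
#'   `bin_start`, `bin_end`, `bin_mid`.
#' @export
assign_bins <- function(centers, bin_width = 400, arms = NULL) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width < 1) {
    abort("`bin_width` must be a single number >= 1")
  }
  origin_of <- bin_origins(arms)
  origin <- purrr::map_dbl(centers$chrom, origin_of)
  offset <- centers$center - origin
  if (is.null(arms) && any(offset < 0)) {
    abort("peak center left of the bin origin but no arm definitions given")
  }
  q_arm <- offset >= 0
  bin <- ifelse(q_arm, floor(offset / bin_width),
                ceiling(-offset / bin_width) - 1)
  bin_start <- ifelse(q_arm, origin + bin * bin_width,
                      origin - (bin + 1) * bin_width)
  dplyr::mutate(centers,
                arm = ifelse(q_arm, "q", "p"),
                bin = as.integer(bin),
                bin_start = bin_start,
                bin_end = bin_start + bin_width,
                bin_mid = bin_start + bin_width / 2)
}

bin_origins <- function(arms) {
  if (is.null(arms)) {
    return(function(chrom) 0)
  }
  if (is.character(arms)) {
    arms <- readr::read_tsv(arms, col_types = readr::cols(
      chrom = readr::col_character(), origin = readr::col_double()),
      progress = FALSE)
  }
  stopifnot(all(c("chrom", "origin") %in% names(arms)))
  lut <- setNames(arms$origin, arms$chrom)
  function(chrom) {
    if (chrom %in% names(lut)) unname(lut[chrom]) else 0
  }
}

#' Call binding sites from binned peak centers
#'
#' The binning baseline: a bin is declared a binding-site location when at
#' least one cell line contributes peak centers from `min_replicates`
#' distinct datasets to it, and constitutive when the supported fraction of
#' cell lines strictly exceeds `constitutive_cutoff` — the same decision
#' rules as [call_sites()], with the bin interval as the region and the bin
#' midpoint as the summit. Compared with density-based calling, bins suffer
#' boundary effects (one locus split across two bins) and amalgamation
#' (several loci merged into one wide bin).
#'
#' @param binned Output of [assign_bins()].
#' @param manifest Manifest tibble.
#' @param min_replicates,constitutive_cutoff See [call_sites()].
#' @return A tibble of binding-site calls as in [call_sites()].
#' @export
call_bins <- function(binned, manifest, min_replicates = 2L,
                      constitutive_cutoff = 0.9) {
  regions <- binned |>
    dplyr::group_by(.data$chrom, .data$arm, .data$bin, .data$bin_start,
                    .data$bin_end, .data$bin_mid) |>
    dplyr::summarise(datasets = list(.data$dataset_id), .groups = "drop") |>
    dplyr::transmute(chrom = .data$chrom, summit = .data$bin_mid,
                     left = .data$bin_start, right = .data$bin_end,
                     datasets = .data$datasets)
  call_sites(regions, manifest, min_replicates = min_replicates,
             constitutive_cutoff = constitutive_cutoff)
}

#' Call binding sites with the fixed-width binning baseline
#'
#' End-to-end baseline driver: reads the manifest's peak files, computes
#' centers, assigns them to bins ([assign_bins()]) and applies the calling
#' rules ([call_bins()]).
#'
#' @inheritParams call_binding_sites
#' @param bin_width Bin size in bp; default 400, the width at which this
#'   baseline localises sites best for typical narrow-peak factors.
#' @param arms Optional arm definitions; see [assign_bins()].
#' @return A `binding_sites` tibble; see [call_binding_sites()].
#' @export
call_binned_sites <- function(manifest, bin_width = 400, arms = NULL,
                              min_replicates = 2L, constitutive_cutoff = 0.9,
                              strict = FALSE) {
  if (is.character(manifest)) {
    manifest <- read_manifest(manifest)
  }
  peaks <- read_all_peaks(manifest, strict = strict)
  params <- list(bin_width = bin_width, min_replicates = min_replicates,
                 constitutive_cutoff = constitutive_cutoff, method = "binning")
  if (nrow(peaks) == 0) {
    warn("no input peaks; returning an empty call set")
    return(new_binding_sites(call_sites(tibble::tibble(), manifest),
                             empty_stats(), params))
  }
  centers <- compute_centers(peaks)
  binned <- assign_bins(centers, bin_width = bin_width, arms = arms)
  calls <- call_bins(binned, manifest, min_replicates = min_replicates,
                     constitutive_cutoff = constitutive_cutoff)
  occupied <- dplyr::distinct(binned, .data$chrom, .data$arm, .data$bin)
  stats <- run_stats(centers, occupied, occupied, calls)
  new_binding_sites(calls, stats, params)
}
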