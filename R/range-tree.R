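#' Partition peak centers into terminal nodes with a binary range tree
#'
#' Recursively splits the sorted peak centers of each chromosome at the
#' midrange (the mean of the minimum and maximum positions): centers strictly
#' below the midrange go to the left child, centers at or above it to the
#' right. A node is kept intact (becomes terminal) when either child of its
#' prospective split would contain peak centers from fewer than
#' `coverage_cutoff` of the available cell lines, so every terminal node of a
#' well-covered chromosome still represents (almost) all cell lines and can
#' be density-analysed on its own. Splitting is also forced to stop when a
#' node holds at most one distinct position.
#'
#' "Available cell lines" means all cell lines in the manifest, genome-wide;
#' a cell line counts as present in a node as soon as one of its datasets
#' contributes a center there. A split requires both children to cover
#' *strictly more than* `coverage_cutoff * n_cell_lines` lines (evaluated on
#' the real-valued product), so every terminal node of a well-covered
#' chromosome represents more than the cutoff fraction of cell lines — the
#' same strict ">90%" convention the constitutive rule uses. With 55 cell
#' lines and a 0.9 cutoff, a child covering 49 lines blocks the split
#' (49 < 49.5) and one covering 50 allows it; with 10 cell lines a child
#' must cover all 10, which keeps the tree from cutting through a tight
#' cluster of centers whose halves would each retain exactly 90% of lines.
#' With `coverage_cutoff = 1`, both children must cover every cell line.
#'
#' @param centers A tibble of peak centers (`chrom`, `center`, `dataset_id`),
#'   e.g. from [compute_centers()]. May span several chromosomes.
#' @param manifest Manifest tibble from [read_manifest()]; defines the
#'   cell-line universe.
#' @param coverage_cutoff Fraction in (0, 1]; default 0.9.
#'
#' @return A tibble with one row per terminal node: `chrom`, `node`,
#'   `node_start`, `node_end`, `n_centers`, `n_cell_lines`,
#'   `cell_line_coverage`, and a `data` list-column holding that node's
#'   centers (`center`, `dataset_id`, sorted by position). Nodes are in
#'   genomic order and jointly contain every input center exactly once.
#' @export
build_terminal_nodes <- function(centers, manifest, coverage_cutoff = 0.9) {
  if (!is.numeric(coverage_cutoff) || length(coverage_cutoff) != 1 ||
      coverage_cutoff <= 0 || coverage_cutoff > 1) {
    abort("`coverage_cutoff` must be a single number in (0, 1]")
  }
  empty <- tibble::tibble(chrom = character(), node = integer(),
                          node_start = double(), node_end = double(),
                          n_centers = integer(), n_cell_lines = integer(),
                          cell_line_coverage = double(), data = list())
  if (nrow(centers) == 0) {
    return(empty)
  }
  line_of <- setNames(manifest$cell_line, manifest$dataset_id)
  unknown <- setdiff(unique(centers$dataset_id), manifest$dataset_id)
  if (length(unknown) > 0) {
    abort(paste0("dataset_id not in manifest: ",
                 paste(unknown, collapse = ", ")))
  }
  n_lines <- length(unique(manifest$cell_line))
  threshold <- coverage_cutoff * n_lines

  centers |>
    dplyr::arrange(.data$chrom, .data$center) |>
    dplyr::group_split(.data$chrom) |>
    purrr::map(function(d) {
      pos <- d$center
      line <- unname(line_of[d$dataset_id])
      spans <- split_ranges(pos, line, threshold, n_lines)
      purrr::map2(spans$lo, spans$hi, function(lo, hi) {
        idx <- lo:hi
        tibble::tibble(
          chrom = d$chrom[1],
          node_start = pos[lo], node_end = pos[hi],
          n_centers = length(idx),
          n_cell_lines = length(unique(line[idx])),
          data = list(tibble::tibble(center = pos[idx],
                                     dataset_id = d$dataset_id[idx]))
        )
      }) |>
        purrr::list_rbind() |>
        dplyr::mutate(node = dplyr::row_number(), .after = "chrom")
    }) |>
    purrr::list_rbind() |>
    dplyr::mutate(
      cell_line_coverage =
        .data$n_cell_lines / length(unique(manifest$cell_line)),
      .after = "n_cell_lines")
}

# Iterative midrange recursion over one chromosome's sorted positions.
# Returns terminal [lo, hi] index ranges in genomic order.
split_ranges <- function(pos, line, threshold, n_lines) {
  # a child permits the split when its coverage strictly exceeds the
  # cutoff (full coverage always suffices, so cutoff = 1 is attainable)
  child_ok <- function(cov) cov > threshold || cov == n_lines
  out_lo <- integer()
  out_hi <- integer()
  stack <- list(c(1L, length(pos)))
  while (length(stack) > 0) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- rng[1]; hi <- rng[2]
    terminal <- FALSE
    if (pos[lo] == pos[hi]) {
      terminal <- TRUE  # <=1 distinct position: midrange makes no progress
    } else {
      mid <- (pos[lo] + pos[hi]) / 2
      # first index at or above the midrange; strictly-less goes left
      cut <- lo + findInterval(mid, pos[lo:hi], left.open = TRUE)
      if (cut <= lo || cut > hi) {
        terminal <- TRUE  # a child would be empty
      } else {
        left_cov <- length(unique(line[lo:(cut - 1L)]))
        right_cov <- length(unique(line[cut:hi]))
        if (!child_ok(left_cov) || !child_ok(right_cov)) {
          terminal <- TRUE
        } else {
          # push right first so the left range is processed next (in-order)
          stack[[length(stack) + 1L]] <- c(cut, hi)
          stack[[length(stack) + 1L]] <- c(lo, cut - 1L)
        }
      }
    }
    if (terminal) {
      out_lo <- c(out_lo, lo)
      out_hi <- c(out_hi, hi)
    }
  }
  ord <- order(out_lo)
  list(lo = out_lo[ord], hi = out_hi[ord])
}
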