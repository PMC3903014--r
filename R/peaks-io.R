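#' Read a dataset manifest
#'
#' The manifest maps every peak file to its biological sample. It is a
#' tab-delimited file with header columns `dataset_id`, `file_path`,
#' `cell_line` and `replicate`; together the rows define the universe of
#' cell lines against which constitutive binding is judged.
#'
#' @param path Path to a tab-delimited manifest file.
#' @param resolve_paths If `TRUE` (default), relative `file_path` entries are
#'   resolved against the manifest's own directory, so a manifest can be moved
#'   together with its peak files.
#'
#' @return A tibble with columns `dataset_id`, `file_path`, `cell_line`,
#'   `replicate`, one row per dataset. `dataset_id` values are guaranteed
#'   unique.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' writeLines(c("dataset_id\tfile_path\tcell_line\treplicate",
#'              "A1\ta1.bed\tA\trep1", "A2\ta2.bed\tA\trep2"), tmp)
#' read_manifest(tmp)
read_manifest <- function(path, resolve_paths = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("manifest file not found: ", path))
  }
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  required <- c("dataset_id", "file_path", "cell_line", "replicate")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  m <- dplyr::select(m, dplyr::all_of(required))
  if (nrow(m) == 0) {
    abort("manifest contains no datasets")
  }
  dup <- m$dataset_id[duplicated(m$dataset_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate dataset_id in manifest: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(m)) {
    abort("manifest contains missing values")
  }
  if (resolve_paths) {
    base <- dirname(path)
    rel <- !grepl("^(/|[A-Za-z]:)", m$file_path)
    m$file_path[rel] <- file.path(base, m$file_path[rel])
  }
  m
}

#' Summarise the cell-line structure of a manifest
#'
#' @param manifest A manifest tibble from [read_manifest()].
#' @return A tibble with one row per cell line and columns `cell_line`,
#'   `n_datasets`.
#' @export
datasets_per_cell_line <- function(manifest) {
  dplyr::count(manifest, .data$cell_line, name = "n_datasets")
}

#' Read called peaks from a BED or narrowPeak file
#'
#' Accepts any tab-delimited BED3+ dialect, including ENCODE narrowPeak
#' (BED6+4); only the first three columns (chrom, start, end) are used and
#' coordinates are taken as 0-based half-open. `track`, `browser` and `#`
#' comment lines are skipped.
#'
#' @param path Path to the peak file.
#' @param dataset_id Key attached to every record from this file.
#' @param strict If `FALSE` (default), malformed records (e.g. `end <= start`)
#'   are skipped with a warning; if `TRUE` they are an error.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `dataset_id`, one
#'   row per peak, in file order.
#' @export
read_peaks <- function(path, dataset_id, strict = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("peak file not found: ", path))
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  empty <- tibble::tibble(chrom = character(), start = double(),
                          end = double(), dataset_id = character())
  if (length(lines) == 0) {
    return(empty)
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          fill = TRUE, colClasses = list(character = 1),
                          showProgress = FALSE)
  if (ncol(dt) < 3) {
    abort(paste0("not a BED3+ file (fewer than 3 columns): ", path))
  }
  chrom <- as.character(dt[[1]])
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad_num <- is.na(start) | is.na(end)
  if (any(bad_num)) {
    abort(paste0("non-numeric coordinates in ", path, " (first bad line ",
                 which(bad_num)[1], ")"))
  }
  bad <- end <= start | start < 0
  if (any(bad)) {
    msg <- paste0(sum(bad), " record(s) with end <= start or start < 0 in ",
                  path)
    if (strict) abort(msg)
    warn(paste0(msg, "; skipped"))
  }
  keep <- !bad
  tibble::tibble(chrom = chrom[keep], start = start[keep], end = end[keep],
                 dataset_id = rep(dataset_id, sum(keep)))
}

#' Read all peak files listed in a manifest
#'
#' @param manifest A manifest tibble from [read_manifest()].
#' @param strict Passed to [read_peaks()].
#' @return A tibble of peaks (`chrom`, `start`, `end`, `dataset_id`) pooled
#'   over every dataset in the manifest.
#' @export
read_all_peaks <- function(manifest, strict = FALSE) {
  purrr::map2(manifest$file_path, manifest$dataset_id, read_peaks,
              strict = strict) |>
    purrr::list_rbind()
}

#' Compute peak centers
#'
#' The center of a peak is half the sum of its start and end coordinates,
#' kept at half-integer resolution (no rounding): it is the one-dimensional
#' datum that all downstream density estimation works on.
#'
#' @param peaks A tibble of peaks with columns `chrom`, `start`, `end` and
#'   (optionally) `dataset_id`.
#' @return A tibble with columns `chrom`, `center`, `dataset_id`.
#' @export
#' @examples
#' compute_centers(tibble::tibble(chrom = "chr1", start = 100, end = 301,
#'                                dataset_id = "A1"))
compute_centers <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$end <= peaks$start)) {
    abort("peaks with end <= start cannot be centered")
  }
  out <- tibble::tibble(chrom = peaks$chrom,
                        center = (peaks$start + peaks$end) / 2)
  out$dataset_id <- if ("dataset_id" %in% names(peaks)) {
    peaks$dataset_id
  } else {
    NA_character_
  }
  out
}

#' Write binding-site calls as BED6+4
#'
#' Emits one line per call: chrom, region start, region end (half-open;
#' zero-width modal regions are written as `[floor(summit), floor(summit)+1)`),
#' a `site_<k>` name, a score of `round(1000 * cell_line_fraction)`, strand
#' `"."`, then the summit coordinate, the number of supporting cell lines,
#' the number of member peak centers, and the constitutive flag as 0/1.
#' Provenance (package version, parameters, timestamp) is recorded in `#`
#' comment headers. A companion TSV with per-chromosome totals is written
#' alongside.
#'
#' @param calls A tibble of binding-site calls as produced by [call_sites()].
#' @param path Output BED path.
#' @param summary_path Output path for the per-chromosome summary table;
#'   default is `path` with a `.summary.tsv` suffix.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(calls, path, summary_path = paste0(path, ".summary.tsv")) {
  calls <- dplyr::arrange(calls, .data$chrom, .data$summit)
  params <- attr(calls, "params")
  hdr <- c(
    paste0("# consite v", as.character(packageVersion("consite")),
           " binding-site calls"),
    paste0("# generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    if (!is.null(params)) {
      paste0("# parameters: ",
             paste(names(params), unlist(params), sep = "=", collapse = " "))
    },
    paste0("# columns: chrom start end name score strand summit ",
           "n_cell_lines n_peak_centers constitutive")
  )
  n <- nrow(calls)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (n > 0) {
    bed_start <- floor(calls$region_start)
    bed_end <- ifelse(calls$region_end > calls$region_start,
                      ceiling(calls$region_end), bed_start + 1)
    body <- paste(calls$chrom, format_coord(bed_start), format_coord(bed_end),
                  paste0("site_", seq_len(n)),
                  round(1000 * calls$cell_line_fraction), ".",
                  format_coord(calls$summit), calls$n_cell_lines,
                  calls$n_peak_centers, as.integer(calls$constitutive),
                  sep = "\t")
    writeLines(body, con)
  }
  smry <- calls |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     n_constitutive = sum(.data$constitutive),
                     .groups = "drop")
  readr::write_tsv(smry, summary_path, progress = FALSE)
  invisible(path)
}

# plain decimal coordinates (no scientific notation, no trailing zeros)
format_coord <- function(x) {
  out <- format(x, scientific = FALSE, trim = TRUE)
  sub("\\.0+$", "", out)
}

#' Read binding-site calls written by [write_sites()]
#'
#' @param path Path to a BED6+4 site file.
#' @return A tibble with the same columns as [call_sites()] output.
#' @export
read_sites <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  cols <- c("chrom", "region_start", "region_end", "name", "score", "strand",
            "summit", "n_cell_lines", "n_peak_centers", "constitutive")
  if (length(lines) == 0) {
    out <- tibble::as_tibble(setNames(rep(list(double()), 10), cols))
    out$chrom <- character()
    out$name <- character()
    out$strand <- character()
    return(out)
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          showProgress = FALSE)
  names(dt) <- cols
  out <- tibble::as_tibble(dt)
  out$constitutive <- as.logical(out$constitutive)
  out$cell_line_fraction <- out$score / 1000
  out
}
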