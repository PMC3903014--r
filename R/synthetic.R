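#' Simulate a multi-cell-line ChIP-seq peak catalog with known truth
#'
#' Emulates the input of a constitutive-binding-site analysis: a set of
#' binding loci planted on one synthetic chromosome, sampled by several cell
#' lines with replicate datasets. Constitutive loci are present in every
#' cell line; cell-line-specific loci in a random proper subset (each line
#' included with probability `specific_presence`, redrawn if the subset
#' comes out empty or complete, so a "specific" locus is never accidentally
#' constitutive); noise peaks are scattered uniformly and independently per
#' dataset. For every dataset of a cell line in a locus's presence set, one
#' peak is emitted with probability `1 - dropout` whose center is the locus
#' position plus rounded Gaussian jitter (sd `jitter_sd`, clipped at +/- 5
#' sd) and whose width is drawn uniformly from `peak_width` (rounded to an
#' even integer, so the emitted interval's half-sum center reproduces the
#' jittered center exactly).
#'
#' Everything is deterministic given `seed`. Peak files (BED6), a manifest
#' TSV and a truth TSV are written under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_cell_lines Number of cell lines; default 10.
#' @param replicates Replicate datasets per cell line; default 2.
#' @param n_constitutive Number of loci present in all cell lines;
#'   default 50.
#' @param n_specific Number of cell-line-specific loci; default 0.
#' @param specific_presence Per-cell-line inclusion probability for specific
#'   loci; default 0.5.
#' @param noise_per_dataset Uniform background peaks per dataset; default 0.
#' @param chrom Chromosome name; default `"chrS"`.
#' @param chrom_length Chromosome length in bp; default 1e6.
#' @param min_spacing Minimum distance between planted loci in bp; default
#'   2000 (several peak widths, so neighbouring loci stay separable).
#' @param jitter_sd Standard deviation of the peak-center jitter around the
#'   locus, in bp; default 20.
#' @param peak_width Length-2 numeric range of peak widths in bp; default
#'   `c(150, 350)`, typical of narrow transcription-factor peaks.
#' @param dropout Probability that a present locus yields no peak in a given
#'   dataset; default 0.
#' @param seed Integer RNG seed; default 1.
#'
#' @return Invisibly, a list of class `sim_peaks`: `truth` (tibble with
#'   `locus_id`, `chrom`, `position`, `kind`, `presence` list-column),
#'   `manifest` (as [read_manifest()] returns), `dir`, and the `config`
#'   actually used.
#' @export
simulate_peaks <- function(out_dir,
                           n_cell_lines = 10, replicates = 2,
                           n_constitutive = 50, n_specific = 0,
                           specific_presence = 0.5, noise_per_dataset = 0,
                           chrom = "chrS", chrom_length = 1e6,
                           min_spacing = 2000, jitter_sd = 20,
                           peak_width = c(150, 350), dropout = 0,
                           seed = 1L) {
  stopifnot(n_cell_lines >= 1, replicates >= 1, n_constitutive >= 0,
            n_specific >= 0, noise_per_dataset >= 0, jitter_sd >= 0,
            dropout >= 0, dropout < 1, length(peak_width) == 2,
            peak_width[1] >= 2, peak_width[2] >= peak_width[1])
  if (min_spacing <= 2 * mean(peak_width)) {
    abort("`min_spacing` must exceed twice the expected peak width")
  }
  if (n_specific > 0 && n_cell_lines < 2) {
    abort("cell-line-specific loci need at least 2 cell lines")
  }
  n_loci <- n_constitutive + n_specific
  margin <- max(peak_width) + 5 * jitter_sd
  usable <- chrom_length - 2 * margin - (n_loci - 1) * min_spacing
  if (n_loci > 0 && usable <= 0) {
    abort("chromosome too short for the requested locus count and spacing")
  }
  set.seed(seed)

  cell_lines <- sprintf("CL%02d", seq_len(n_cell_lines))
  manifest <- tidyr::expand_grid(cell_line = cell_lines,
                                 replicate = sprintf("rep%d", seq_len(replicates)))
  manifest <- tibble::tibble(
    dataset_id = paste0(manifest$cell_line, "_", manifest$replicate),
    file_path = paste0(manifest$cell_line, "_", manifest$replicate, ".bed"),
    cell_line = manifest$cell_line,
    replicate = manifest$replicate
  )

  # loci: sorted uniforms stretched to guarantee min_spacing, kinds shuffled
  truth <- tibble::tibble(locus_id = integer(), chrom = character(),
                          position = double(), kind = character(),
                          presence = list())
  if (n_loci > 0) {
    position <- round(sort(runif(n_loci, 0, usable)) +
                        min_spacing * (seq_len(n_loci) - 1) + margin)
    kind <- sample(rep(c("constitutive", "specific"),
                       c(n_constitutive, n_specific)))
    presence <- purrr::map(kind, function(k) {
      if (k == "constitutive") {
        return(cell_lines)
      }
      repeat {
        inc <- runif(n_cell_lines) < specific_presence
        if (any(inc) && !all(inc)) {
          return(cell_lines[inc])
        }
      }
    })
    truth <- tibble::tibble(locus_id = seq_len(n_loci), chrom = chrom,
                            position = position, kind = kind,
                            presence = presence)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clip <- floor(5 * jitter_sd)
  for (i in seq_len(nrow(manifest))) {
    ds <- manifest[i, ]
    present <- purrr::map_lgl(truth$presence, ~ ds$cell_line %in% .x)
    emitted <- present & runif(nrow(truth)) >= dropout
    locus_pos <- truth$position[emitted]
    jitter <- pmin(pmax(round(rnorm(length(locus_pos), 0, jitter_sd)),
                        -clip), clip)
    centers <- locus_pos + jitter
    if (noise_per_dataset > 0) {
      centers <- c(centers, round(runif(noise_per_dataset,
                                        margin, chrom_length - margin)))
    }
    half <- round(runif(length(centers), peak_width[1], peak_width[2]) / 2)
    start <- pmax(centers - half, 0)
    end <- centers + half
    ord <- order(start)
    bed <- tibble::tibble(chrom = chrom, start = start[ord], end = end[ord],
                          name = paste0(ds$dataset_id, "_pk",
                                        seq_along(centers)),
                          score = 0L, strand = ".")
    readr::write_tsv(bed, file.path(out_dir, ds$file_path),
                     col_names = FALSE, progress = FALSE)
  }

  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  truth_flat <- dplyr::mutate(
    truth, presence = purrr::map_chr(.data$presence, paste, collapse = ","))
  readr::write_tsv(truth_flat, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)

  manifest$file_path <- file.path(out_dir, manifest$file_path)
  invisible(structure(
    list(truth = truth, manifest = manifest, dir = out_dir,
         config = list(n_cell_lines = n_cell_lines, replicates = replicates,
                       n_constitutive = n_constitutive,
                       n_specific = n_specific,
                       specific_presence = specific_presence,
                       noise_per_dataset = noise_per_dataset, chrom = chrom,
                       chrom_length = chrom_length,
                       min_spacing = min_spacing, jitter_sd = jitter_sd,
                       peak_width = peak_width, dropout = dropout,
                       seed = seed)),
    class = "sim_peaks"))
}

#' Read a truth table written by [simulate_peaks()]
#'
#' @param path Path to `truth.tsv`.
#' @return A tibble with `locus_id`, `chrom`, `position`, `kind` and a
#'   `presence` list-column of cell lines.
#' @export
read_truth <- function(path) {
  t <- readr::read_tsv(path, col_types = readr::cols(
    locus_id = readr::col_integer(), chrom = readr::col_character(),
    position = readr::col_double(), kind = readr::col_character(),
    presence = readr::col_character()), progress = FALSE)
  t$presence <- strsplit(t$presence, ",", fixed = TRUE)
  t
}

#' Score recovery of planted constitutive loci
#'
#' Matches constitutive calls to planted constitutive loci greedily, nearest
#' pair first, one-to-one, within `match_radius`. Recall is the matched
#' fraction of planted constitutive loci; precision the matched fraction of
#' constitutive calls.
#'
#' @param truth Truth tibble from [simulate_peaks()] or [read_truth()].
#' @param calls A binding-site call tibble ([call_binding_sites()] etc.).
#' @param match_radius Maximum |summit - locus| for a match, in bp;
#'   default 100.
#' @return A one-row tibble (class `recovery_report`): `n_truth`, `n_calls`,
#'   `n_matched`, `recall`, `precision`, `median_distance`,
#'   `max_distance`, with the per-match distance table in
#'   `attr(, "matches")`.
#' @export
score_recovery <- function(truth, calls, match_radius = 100) {
  truth_pos <- truth$position[truth$kind == "constitutive"]
  cons <- dplyr::filter(tibble::as_tibble(unclass_calls(calls)),
                        .data$constitutive)
  call_pos <- cons$summit
  pairs <- tidyr::expand_grid(truth_idx = seq_along(truth_pos),
                              call_idx = seq_along(call_pos))
  pairs$distance <- abs(truth_pos[pairs$truth_idx] - call_pos[pairs$call_idx])
  pairs <- pairs |>
    dplyr::filter(.data$distance <= match_radius) |>
    dplyr::arrange(.data$distance)
  used_t <- logical(length(truth_pos))
  used_c <- logical(length(call_pos))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ti <- pairs$truth_idx[i]
    ci <- pairs$call_idx[i]
    if (!used_t[ti] && !used_c[ci]) {
      used_t[ti] <- TRUE
      used_c[ci] <- TRUE
      keep[i] <- TRUE
    }
  }
  matches <- pairs[keep, ]
  matches$truth_position <- truth_pos[matches$truth_idx]
  matches$call_summit <- call_pos[matches$call_idx]
  out <- tibble::tibble(
    n_truth = length(truth_pos),
    n_calls = length(call_pos),
    n_matched = nrow(matches),
    recall = if (length(truth_pos) > 0) nrow(matches) / length(truth_pos) else NA_real_,
    precision = if (length(call_pos) > 0) nrow(matches) / length(call_pos) else NA_real_,
    median_distance = if (nrow(matches) > 0) median(matches$distance) else NA_real_,
    max_distance = if (nrow(matches) > 0) max(matches$distance) else NA_real_
  )
  structure(out, matches = matches,
            class = c("recovery_report", class(out)))
}

#' Plot the distance CDF of matched constitutive calls
#'
#' The empirical cumulative distribution of |call summit - planted locus|
#' over matched pairs: the proportion of constitutive calls within distance
#' d of their nearest planted locus, as a function of d.
#'
#' @param object A `recovery_report` from [score_recovery()], or a list of
#'   them (named, e.g. by method or parameter) to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_report <- function(object, ...) {
  plot_distance_cdf(list(calls = object))
}

#' @rdname autoplot.recovery_report
#' @param reports A named list of `recovery_report` objects.
#' @export
plot_distance_cdf <- function(reports, ...) {
  d <- purrr::imap(reports, function(r, nm) {
    m <- attr(r, "matches")
    tibble::tibble(set = nm, distance = sort(m$distance),
                   proportion = seq_along(m$distance) / max(1, r$n_calls))
  }) |>
    purrr::list_rbind()
  ggplot2::ggplot(d, ggplot2::aes(.data$distance, .data$proportion,
                                  colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance to nearest planted locus (bp)",
                  y = "proportion of constitutive calls") +
    ggplot2::theme_minimal()
}
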