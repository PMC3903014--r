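# In-code fixtures shared across the suite.

# A manifest of n_lines cell lines x reps replicate datasets, no files.
make_manifest <- function(n_lines = 2, reps = 2) {
  grid <- expand.grid(rep = seq_len(reps), line = seq_len(n_lines))
  line <- sprintf("CL%02d", grid$line)
  replicate <- sprintf("rep%d", grid$rep)
  tibble::tibble(dataset_id = paste0(line, "_", replicate),
                 file_path = paste0(line, "_", replicate, ".bed"),
                 cell_line = line, replicate = replicate)
}

# Centers tibble on one chromosome from parallel vectors.
make_centers <- function(position, dataset_id, chrom = "chr1") {
  tibble::tibble(chrom = chrom, center = as.numeric(position),
                 dataset_id = dataset_id)
}

# Random centers over a manifest: each dataset contributes k centers
# uniform on [0, span].
random_centers <- function(manifest, k = 5, span = 1e5, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom,
    center = round(runif(k * nrow(manifest), 0, span)),
    dataset_id = rep(manifest$dataset_id, each = k)
  )
}

# Independent brute-force mode oracle: all local maxima/minima of the
# density on a dense grid. Used to verify the hill-climbing implementation,
# never to implement it.
grid_modes <- function(positions, h, step = h / 1000, pad = 4 * h) {
  grid <- seq(min(positions) - pad, max(positions) + pad, by = step)
  u <- outer(grid, positions, "-") / h
  d <- rowMeans(dnorm(u)) / h
  s <- sign(diff(d))
  turn <- diff(s)
  list(maxima = grid[which(turn < 0) + 1L],
       minima = grid[which(turn > 0) + 1L])
}

# One shared mid-size simulation per test run (50 constitutive loci,
# 10 cell lines x 2 replicates, 20 bp jitter), reused by several files.
sim_cache <- new.env(parent = emptyenv())

get_sim <- function(which = c("clean", "noisy")) {
  which <- match.arg(which)
  if (is.null(sim_cache[[which]])) {
    dir <- file.path(tempdir(), paste0("consite_sim_", which))
    sim_cache[[which]] <- if (which == "clean") {
      simulate_peaks(dir, seed = 7)
    } else {
      simulate_peaks(dir, n_specific = 30, noise_per_dataset = 100, seed = 7)
    }
  }
  sim_cache[[which]]
}

get_calls <- function(which = c("clean", "noisy"), bandwidth = 100, ...) {
  which <- match.arg(which)
  key <- paste0("calls_", which, "_h", bandwidth)
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- call_binding_sites(get_sim(which)$manifest,
                                           bandwidth = bandwidth, ...)
  }
  sim_cache[[key]]
}

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
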