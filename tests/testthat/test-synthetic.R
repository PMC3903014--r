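test_that("a dropout-free simulation emits one peak per dataset per locus", {
  dir <- tempfile("sim")
  sim <- simulate_peaks(dir, n_cell_lines = 10, replicates = 2,
                        n_constitutive = 20, jitter_sd = 20, seed = 7)
  expect_equal(nrow(sim$truth), 20)
  expect_true(all(sim$truth$kind == "constitutive"))
  peaks <- read_all_peaks(sim$manifest)
  expect_equal(nrow(peaks), 20 * 20)  # 20 loci x (10 cell lines x 2 reps)
  expect_true(all(table(peaks$dataset_id) == 20))

  # peak centers are exact half-sums within 5 sd of their locus
  centers <- compute_centers(peaks)
  nearest <- vapply(centers$center,
                    function(p) min(abs(sim$truth$position - p)), numeric(1))
  expect_true(all(nearest <= 5 * 20))
  # planted loci honour the spacing floor
  expect_true(all(diff(sort(sim$truth$position)) >= 2000))
})

test_that("simulation output is byte-identical for a fixed seed", {
  d1 <- tempfile("sim_a")
  d2 <- tempfile("sim_b")
  simulate_peaks(d1, n_constitutive = 10, n_specific = 5,
                 noise_per_dataset = 10, seed = 123)
  simulate_peaks(d2, n_constitutive = 10, n_specific = 5,
                 noise_per_dataset = 10, seed = 123)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  d3 <- tempfile("sim_c")
  simulate_peaks(d3, n_constitutive = 10, n_specific = 5,
                 noise_per_dataset = 10, seed = 124)
  expect_false(identical(readLines(file.path(d1, "truth.tsv")),
                         readLines(file.path(d3, "truth.tsv"))))
})

test_that("dropout thins peak counts like a binomial", {
  # 1 locus, 10 cell lines x 2 reps, dropout 0.5: emitted ~ Binomial(20, 0.5)
  counts <- vapply(1:200, function(s) {
    sim <- simulate_peaks(tempfile("drop"), n_cell_lines = 10,
                          replicates = 2, n_constitutive = 1,
                          dropout = 0.5, seed = s)
    nrow(read_all_peaks(sim$manifest))
  }, numeric(1))
  # mean within 99% normal bounds for 200 draws of Binomial(20, 0.5)
  se <- sqrt(20 * 0.25 / 200)
  expect_lt(abs(mean(counts) - 10), 2.58 * se)
  expect_true(all(counts >= 0 & counts <= 20))
})

test_that("specific loci are present in a proper nonempty subset of lines", {
  sim <- simulate_peaks(tempfile("spec"), n_constitutive = 5,
                        n_specific = 30, seed = 42)
  spec <- sim$truth[sim$truth$kind == "specific", ]
  sizes <- lengths(spec$presence)
  expect_true(all(sizes >= 1 & sizes <= 9))
  cons <- sim$truth[sim$truth$kind == "constitutive", ]
  expect_true(all(lengths(cons$presence) == 10))
  # the truth table round-trips through its TSV form
  back <- read_truth(file.path(sim$dir, "truth.tsv"))
  expect_equal(back$position, sim$truth$position)
  expect_equal(back$presence, sim$truth$presence)
})

test_that("recovery scoring matches greedily and counts correctly", {
  truth <- tibble::tibble(locus_id = 1:3, chrom = "chrS",
                          position = c(1000, 5000, 9000),
                          kind = "constitutive", presence = list("x"))
  fake_calls <- function(summits) {
    tibble::tibble(chrom = "chrS", summit = summits,
                   region_start = summits, region_end = summits,
                   n_cell_lines = 10L, cell_line_fraction = 1,
                   n_peak_centers = 20L, constitutive = TRUE)
  }
  perfect <- score_recovery(truth, fake_calls(c(1000, 5000, 9000)))
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$median_distance, 0)

  shifted <- score_recovery(truth, fake_calls(c(1005, 5005, 9005)),
                            match_radius = 25)
  expect_equal(shifted$recall, 1)
  expect_equal(shifted$median_distance, 5)

  spurious <- score_recovery(truth, fake_calls(c(1000, 5000, 9000, 50000)))
  expect_equal(spurious$recall, 1)
  expect_equal(spurious$precision, 3 / 4)
  missing <- score_recovery(truth, fake_calls(c(1000, 5000)))
  expect_equal(missing$recall, 2 / 3)
})

test_that("summit error grows with the planted jitter", {
  med_err <- vapply(c(5, 60), function(sd) {
    errs <- vapply(1:3, function(s) {
      sim <- simulate_peaks(tempfile("jit"), n_constitutive = 20,
                            jitter_sd = sd, seed = 100 + s)
      rec <- score_recovery(sim$truth,
                            call_binding_sites(sim$manifest),
                            match_radius = 200)
      rec$median_distance
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(med_err[1], med_err[2])
})
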