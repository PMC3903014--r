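test_that("the density matches Gaussian mixture closed forms", {
  m1 <- kde_model(0, 100)
  expect_equal(kde_density(m1, 0), (2 * pi)^(-1 / 2) / 100,
               tolerance = 1e-12)
  m2 <- kde_model(c(0, 200), 100)
  expect_equal(kde_density(m2, 100),
               2 * (2 * pi)^(-1 / 2) * exp(-1 / 2) / (2 * 100),
               tolerance = 1e-12)
  # mirror symmetry of an equal pair, any bandwidth
  for (h in c(10, 100, 1000)) {
    mh <- kde_model(c(0, 200), h)
    expect_equal(kde_density(mh, 50), kde_density(mh, 150),
                 tolerance = 1e-12)
  }
  expect_error(kde_model(c(0, 1), -5), "bandwidth")
  expect_error(kde_model(numeric(0), 10), "positions")
})

test_that("mode finding handles degenerate and well-separated configurations", {
  # single component
  ms <- find_modes(kde_model(1000, 100))
  expect_equal(ms$maxima, 1000)
  expect_length(ms$minima, 0)

  # equal pair closer than 2h: unimodal with the mode at the midpoint
  ms2 <- find_modes(kde_model(c(0, 50), 100))
  expect_equal(ms2$maxima, 25, tolerance = 1e-6)
  expect_length(ms2$minima, 0)

  # pair separated by 10h: a mode essentially at each point, antimode between
  ms3 <- find_modes(kde_model(c(0, 1000), 100))
  expect_length(ms3$maxima, 2)
  expect_equal(ms3$maxima, c(0, 1000), tolerance = 1e-3)
  expect_equal(ms3$minima, 500, tolerance = 1e-6)

  # tidy() interleaves positions in order
  td <- tidy(ms3)
  expect_equal(td$type, c("maximum", "minimum", "maximum"))
  expect_true(all(diff(td$position) > 0))
})

test_that("summits agree with a dense-grid brute-force oracle", {
  set.seed(21)
  for (i in 1:25) {
    h <- sample(c(50, 100, 400), 1)
    n <- sample(2:50, 1)
    x <- round(runif(n, 0, 20 * h))
    found <- find_modes(kde_model(x, h))
    oracle <- grid_modes(x, h)
    expect_equal(length(found$maxima), length(oracle$maxima))
    expect_lt(max(abs(found$maxima - oracle$maxima)), h / 100)
    # strict alternation: max, min, max, ..., max
    expect_length(found$minima, length(found$maxima) - 1)
    if (length(found$minima) > 0) {
      inter <- as.vector(rbind(found$maxima,
                               c(found$minima, Inf)))
      expect_true(all(diff(inter[-length(inter)]) > 0))
    }
  }
})

test_that("mode count is non-increasing in bandwidth and bounded by distinct points", {
  set.seed(22)
  for (i in 1:10) {
    x <- round(runif(sample(3:30, 1), 0, 3000))
    counts <- vapply(c(20, 40, 80, 160, 320, 640),
                     function(h) length(find_modes(kde_model(x, h))$maxima),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
    expect_lte(counts[1], length(unique(x)))
    expect_gte(counts[length(counts)], 1)
  }
})

test_that("an equal pair is unimodal exactly when separation <= 2h", {
  set.seed(23)
  for (i in 1:10) {
    h <- runif(1, 20, 300)
    below <- find_modes(kde_model(c(0, 1.8 * h), h))
    above <- find_modes(kde_model(c(0, 2.2 * h), h))
    expect_length(below$maxima, 1)
    expect_equal(below$maxima, 0.9 * h, tolerance = 1e-3 * h)
    expect_length(above$maxima, 2)
  }
  # flat inflection at exactly 2h collapses to a single midpoint mode
  # (convergence is sublinear on the flat shoulder, hence the looser bound)
  ms <- find_modes(kde_model(c(0, 200), 100))
  expect_length(ms$maxima, 1)
  expect_lt(abs(ms$maxima - 100), 0.5)
})

test_that("shifting all points shifts every mode and bound by the same amount", {
  set.seed(24)
  x <- round(runif(12, 0, 2000))
  h <- 80
  base_modes <- find_modes(kde_model(x, h))
  base_regs <- delineate_regions(kde_model(x, h), base_modes)
  for (delta in c(-5000, 1e6)) {
    m2 <- kde_model(x + delta, h)
    shifted <- find_modes(m2)
    expect_equal(shifted$maxima, base_modes$maxima + delta, tolerance = 1e-6)
    expect_equal(shifted$minima, base_modes$minima + delta, tolerance = 1e-6)
    regs <- delineate_regions(m2, shifted)
    expect_equal(regs$left, base_regs$left + delta)
    expect_equal(regs$right, base_regs$right + delta)
  }
})

test_that("modal regions partition the sample points between antimodes", {
  # all points in one basin
  m <- kde_model(c(0, 50), 100)
  r <- delineate_regions(m, find_modes(m))
  expect_equal(nrow(r), 1)
  expect_equal(c(r$left, r$right), c(0, 50))
  expect_equal(r$n_members, 2L)

  # two singleton basins: both regions have width zero
  m2 <- kde_model(c(0, 1000), 100)
  r2 <- delineate_regions(m2, find_modes(m2))
  expect_equal(r2$left, r2$right)
  expect_equal(r2$summit, c(0, 1000), tolerance = 1e-3)

  # a three-point basin next to a singleton
  m3 <- kde_model(c(0, 40, 60, 1000), 100)
  r3 <- delineate_regions(m3, find_modes(m3))
  expect_equal(nrow(r3), 2)
  expect_equal(c(r3$left[1], r3$right[1]), c(0, 60))
  expect_equal(c(r3$left[2], r3$right[2]), c(1000, 1000))
  expect_equal(r3$n_members, c(3L, 1L))

  # property: members are disjoint and exhaustive on random instances
  set.seed(25)
  for (i in 1:10) {
    x <- round(runif(sample(2:40, 1), 0, 5000))
    mod <- kde_model(x, 60)
    regs <- delineate_regions(mod, find_modes(mod))
    members <- sort(unlist(regs$members))
    expect_equal(members, seq_along(mod$x))
    expect_true(all(regs$left <= regs$summit & regs$summit <= regs$right))
  }
})
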