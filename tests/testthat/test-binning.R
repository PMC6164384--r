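# nmr_binning: schemes, bin lookup, joint indexing, vectorization,
# matrix assembly and the file formats.

test_that("schemes reproduce the published descriptor counts", {
  counts <- list(list("13C", 1.5, 133L), list("13C", 1.0, 200L),
                 list("13C", 0.5, 400L), list("1H", 0.1, 120L),
                 list("1H", 0.05, 240L))
  for (cs in counts) {
    expect_identical(make_scheme(cs[[1]], cs[[2]])$n_bins, cs[[3]])
  }
  # joint schemes: 120 + 400 = 520 and 240 + 400 = 640
  expect_identical(make_scheme("1H", 0.1)$n_bins +
                     make_scheme("13C", 0.5)$n_bins, 520L)
  expect_identical(make_scheme("1H", 0.05)$n_bins +
                     make_scheme("13C", 0.5)$n_bins, 640L)
  # the published 61-bin 0.2 ppm 1H scheme needs the explicit override
  expect_identical(make_scheme("1H", 0.2)$n_bins, 60L)
  expect_identical(make_scheme("1H", 0.2, n_bins = 61)$n_bins, 61L)
})

test_that("make_scheme validates input and handles the one-bin edge", {
  expect_error(make_scheme("1H", 0), "positive")
  expect_error(make_scheme("1H", -0.1), "positive")
  expect_error(make_scheme("1H", 5, span = c(0, 1)), "shorter than one bin")
  expect_identical(make_scheme("1H", 12, origin = 0)$n_bins, 1L)
})

test_that("bin_index follows the half-open upper-tie convention", {
  sh <- make_scheme("1H", 0.1)
  expect_identical(bin_index(sh, 1.35), 14L)
  expect_identical(bin_index(sh, -0.5), NA_integer_)
  expect_identical(bin_index(sh, 1.4019), 15L)  # exact edge -> upper bin
  expect_identical(bin_index(sh, sh$origin), 1L)
  expect_identical(bin_index(sh, sh$origin + 120 * 0.1), NA_integer_)
  expect_error(bin_index(sh, NaN), "finite")
})

test_that("every in-range shift maps to exactly one bin whose bounds contain it", {
  for (s in list(make_scheme("1H", 0.1), make_scheme("13C", 1.5),
                 make_scheme("1H", 0.2, n_bins = 61))) {
    shifts <- seq(s$origin, s$origin + s$n_bins * s$width - s$width / 20,
                  by = s$width / 10)
    k <- bin_index(s, shifts)
    expect_false(anyNA(k))
    lo <- s$origin + (k - 1) * s$width
    expect_true(all(shifts >= lo - 1e-9 & shifts < lo + s$width + 1e-9))
    # partition: adjacent resolution steps never skip a bin
    expect_true(all(diff(k) %in% c(0L, 1L)))
  }
})

test_that("joint_bounds reproduces the published bin intervals", {
  sh <- make_scheme("1H", 0.1)
  sc <- make_scheme("13C", 0.5)
  b14 <- joint_bounds(sh, sc, 14)
  expect_identical(b14$nucleus, "1H")
  expect_equal(b14$lo, 1.3019, tolerance = 1e-9)
  expect_equal(b14$hi, 1.4019, tolerance = 1e-9)
  b271 <- joint_bounds(sh, sc, 271)  # = 120 + 151st carbon bin
  expect_identical(b271$nucleus, "13C")
  expect_equal(b271$lo, 74.9927, tolerance = 1e-9)
  expect_equal(b271$hi, 75.4927, tolerance = 1e-9)
  b121 <- joint_bounds(sh, sc, 121)  # first 13C bin
  expect_identical(b121$nucleus, "13C")
  expect_equal(b121$lo, -0.0073, tolerance = 1e-9)
  expect_error(joint_bounds(sh, sc, 521), "1..520")
})

test_that("joint_bounds and bin_index are inverse on a sweep of shifts", {
  sh <- make_scheme("1H", 0.1)
  sc <- make_scheme("13C", 0.5)
  set.seed(11)
  shifts_h <- runif(200, sh$origin, sh$origin + sh$n_bins * sh$width - 1e-6)
  for (s in shifts_h[1:20]) {
    j <- bin_index(sh, s)
    b <- joint_bounds(sh, sc, j)
    expect_true(b$lo <= s && s < b$hi)
  }
  shifts_c <- runif(20, sc$origin, sc$origin + sc$n_bins * sc$width - 1e-6)
  for (s in shifts_c) {
    j <- bin_index(sc, s) + sh$n_bins
    b <- joint_bounds(sh, sc, j)
    expect_identical(b$nucleus, "13C")
    expect_true(b$lo <= s && s < b$hi)
  }
})

test_that("vectorize_peaks handles the three modes and out-of-range peaks", {
  sch <- default_schemes()
  empty <- vectorize_peaks(peak_list("e"), sch$h, sch$c)
  expect_length(empty, 520)
  expect_true(all(empty == 0))

  pl <- peak_list("s1", c("1H", "13C"), c(1.35, 75.2))
  v <- vectorize_peaks(pl, sch$h, sch$c, "binary")
  expect_equal(unname(which(v == 1)), c(14L, 271L))
  expect_equal(sum(v), 2)

  two <- peak_list("s2", c("1H", "1H"), c(1.31, 1.39), c(2, 3))
  expect_equal(unname(vectorize_peaks(two, sch$h, sch$c, "count")[14]), 2)
  expect_equal(unname(vectorize_peaks(two, sch$h, sch$c, "binary")[14]), 1)
  expect_equal(unname(vectorize_peaks(two, sch$h, sch$c, "intensity")[14]), 5)

  oor <- peak_list("s3", c("1H", "1H"), c(-3, 1.35))
  expect_warning(v3 <- vectorize_peaks(oor, sch$h, sch$c), "dropped 1 peak")
  expect_equal(sum(v3), 1)
  expect_error(peak_list("s4", "2H", 1.0), "unknown nucleus")
})

test_that("binary vectorization is idempotent under peak duplication; count is additive", {
  sch <- default_schemes()
  set.seed(3)
  sh <- runif(30, 0.1, 9)
  pl1 <- peak_list("a", rep("1H", 30), sh)
  pl2 <- peak_list("a", rep("1H", 60), c(sh, sh))
  expect_equal(vectorize_peaks(pl1, sch$h, sch$c, "binary"),
               vectorize_peaks(pl2, sch$h, sch$c, "binary"))
  expect_equal(vectorize_peaks(pl2, sch$h, sch$c, "count"),
               2 * vectorize_peaks(pl1, sch$h, sch$c, "count"))
})

test_that("solvent mask drops peaks inside the exclusion windows only", {
  sch <- default_schemes()
  pl <- peak_list("s", c("1H", "1H", "13C"), c(7.26, 1.35, 77.0))
  v <- vectorize_peaks(pl, sch$h, sch$c, mask = solvent_mask())
  expect_equal(sum(v), 1)
  expect_equal(unname(which(v == 1)), 14L)
})

test_that("build_matrix assembles aligned matrices with full headers", {
  sch <- default_schemes()
  pls <- list(peak_list("a", "1H", 1.35), peak_list("b", "13C", 75.2))
  dm <- build_matrix(pls, sch$h, sch$c)
  expect_identical(dim(dm$values), c(2L, 520L))
  expect_identical(rownames(dm$values), c("a", "b"))
  expect_match(colnames(dm$values)[14], "H_0014\\[1.3019,1.4019\\)")
  expect_equal(dm$values["a", 14], 1)
  expect_equal(dm$values["b", 271], 1)

  wide <- build_matrix(pls, make_scheme("1H", 0.05), sch$c)
  expect_identical(ncol(wide$values), 640L)

  none <- build_matrix(list(), sch$h, sch$c)
  expect_identical(dim(none$values), c(0L, 520L))
  expect_length(colnames(none$values), 520)

  expect_error(build_matrix(list(peak_list("a"), peak_list("a")),
                            sch$h, sch$c), "duplicate")
})

test_that("peak-list and descriptor-matrix CSV round-trips preserve content", {
  sch <- default_schemes()
  sim <- small_spectra_sim(n = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_peaklist_csv(sim$peaklists, path)
  back <- read_peaklist_csv(path)
  expect_length(back, 8)
  dm1 <- build_matrix(sim$peaklists, sch$h, sch$c)
  dm2 <- build_matrix(back, sch$h, sch$c)
  expect_equal(dm1$values, dm2$values)

  mpath <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(dm1, mpath)
  m <- read_matrix_csv(mpath)
  expect_equal(unname(m), unname(dm1$values))
  expect_identical(colnames(m), colnames(dm1$values))
})

test_that("the JCAMP-DX peak-table reader maps to a peak list", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=PTM-420_F4_F15",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR PEAK TABLE",
    "##.OBSERVE NUCLEUS=^1H",
    "##PEAK TABLE=(XY..XY)",
    "1.35, 104.2  4.31, 55.0",
    "7.25, 12.5",
    "##END="), path)
  pl <- read_jcampdx(path)
  expect_s3_class(pl, "peak_list")
  expect_identical(pl$sample_id, "PTM-420_F4_F15")
  expect_identical(unique(pl$peaks$nucleus), "1H")
  expect_equal(pl$peaks$shift, c(1.35, 4.31, 7.25))
  expect_equal(pl$peaks$intensity, c(104.2, 55.0, 12.5))
  expect_error(read_jcampdx(path, nucleus = "13C"), NA)
})
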