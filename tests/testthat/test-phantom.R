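test_that("a phantom with all perturbations off is the constant baseline", {
  p <- phantom_params(noise_sd = 0, hotspot_amplitude = 0,
                      vessel_amplitude = 0)
  s <- generate_phantom(p)
  expect_true(all(s$temperature == 33.0))
  expect_identical(s$label, -1L)
  expect_true(all(s$gray == 0L))   # degenerate gray range maps to zeros
})

test_that("a noise-free hotspot raises the mirrored difference by its amplitude", {
  p <- phantom_params(noise_sd = 0, hotspot_amplitude = 1.5,
                      hotspot_side = "left", seed = 3)
  s <- generate_phantom(p)
  expect_identical(s$label, 1L)
  tm <- s$temperature
  d <- abs(tm - tm[, ncol(tm):1])
  expect_equal(max(d), 1.5, tolerance = 1e-2)
  # the elevation sits on the requested side only
  left_max <- max(tm[, 1:(ncol(tm) / 2)])
  right_max <- max(tm[, (ncol(tm) / 2 + 1):ncol(tm)])
  expect_gt(left_max, right_max + 1)
})

test_that("phantom generation is bit-reproducible, down to exported bytes", {
  p <- phantom_params(hotspot_amplitude = 2, hotspot_side = "right",
                      vessel_amplitude = 0.8, vessel_count = 2, seed = 42)
  s1 <- generate_phantom(p)
  s2 <- generate_phantom(p)
  expect_identical(s1$temperature, s2$temperature)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_temperature_csv(s1$temperature, f1)
  write_temperature_csv(s2$temperature, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("negatives are mirror-symmetric up to the midline column", {
  s <- generate_phantom(phantom_params(noise_sd = 0.3, seed = 8))
  tm <- s$temperature
  d <- abs(tm - tm[, ncol(tm):1])
  expect_lt(max(d), 1e-12)
  # independent-noise mode breaks the exact symmetry
  s2 <- generate_phantom(phantom_params(noise_sd = 0.3, seed = 8,
                                        mirrored_noise = FALSE))
  d2 <- abs(s2$temperature - s2$temperature[, ncol(s2$temperature):1])
  expect_gt(max(d2), 0.01)
})

test_that("datasets have the requested composition and reproduce exactly", {
  man <- generate_dataset(46, 44, seed = 7)
  expect_identical(nrow(man), 90L)
  expect_identical(sum(man$label == 1), 46L)
  expect_identical(sum(man$label == -1), 44L)
  expect_true(all(man$hotspot_side[man$label == -1] == "none"))
  man2 <- generate_dataset(46, 44, seed = 7)
  expect_identical(man$seed, man2$seed)
  expect_identical(man$sample[[13]]$temperature,
                   man2$sample[[13]]$temperature)

  man3 <- generate_dataset(0, 10, seed = 1)
  expect_true(all(man3$label == -1))
})

test_that("dataset export writes a readable manifest and images", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(2, 2, phantom_params(height = 32, width = 32),
                          seed = 5, dir = dir)
  files <- list.files(dir)
  expect_true("manifest.csv" %in% files)
  expect_length(grep("\\.png$", files), 4L)
  disk <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_identical(disk$id, man$id)
  reread <- load_gray_image(man$temp_path[1])
  expect_equal(reread, man$sample[[1]]$temperature, tolerance = 1e-4)
  expect_identical(load_gray_image(man$png_path[1]), man$sample[[1]]$gray)
})

test_that("the asymmetry screen flags strictly above threshold", {
  sym <- matrix(rep(c(30, 31, 31, 30), each = 8), 8, 4)
  r <- asymmetry_screen(sym)
  expect_false(r$flagged)
  expect_equal(r$max_diff, 0)

  hot <- generate_phantom(phantom_params(noise_sd = 0, hotspot_amplitude = 1.5,
                                         hotspot_side = "left", seed = 2))
  expect_true(asymmetry_screen(hot$temperature)$flagged)

  # a step of exactly 1 degC between the halves: max smoothed mirrored
  # difference is exactly 1.0, which the strict > does not flag
  step <- cbind(matrix(31, 16, 8), matrix(30, 16, 8))
  r2 <- asymmetry_screen(step, threshold = 1.0)
  expect_equal(r2$max_diff, 1.0)
  expect_false(r2$flagged)
  expect_true(asymmetry_screen(step, threshold = 0.99)$flagged)
})

test_that("screen sensitivity grows with hotspot amplitude at fixed noise", {
  rates <- sapply(c(0.5, 1.5, 3.0), function(a) {
    flags <- sapply(1:8, function(s) {
      ph <- generate_phantom(phantom_params(noise_sd = 0.3,
                                            hotspot_amplitude = a,
                                            hotspot_side = "left",
                                            seed = 1000 + s))
      asymmetry_screen(ph$temperature)$max_diff
    })
    mean(flags > 1)
  })
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})
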