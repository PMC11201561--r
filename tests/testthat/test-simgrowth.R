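test_that("sampled nodule parameters satisfy the cohort invariants and are deterministic", {
  cfg <- simulator_config()
  for (lab in c("benign", "malignant")) {
    p1 <- sample_nodule_params(7, lab, cfg)
    p2 <- sample_nodule_params(7, lab, cfg)
    expect_identical(p1, p2)
    expect_gte(p1$diameter_mm, 4); expect_lte(p1$diameter_mm, 30)
    if (lab == "benign") expect_true(is.na(p1$vdt_days))
    if (p1$margin == "smooth") expect_identical(p1$spicule_count, 0L)
  }
  # exhaustive scan of many malignant draws: doubling times stay in range
  vdts <- vapply(seq_len(2000), function(i)
    sample_nodule_params(i, "malignant", cfg)$vdt_days, numeric(1))
  expect_true(all(vdts >= 180 & vdts <= 1460))
  # benign draws never get a doubling time
  ben <- vapply(seq_len(200), function(i)
    sample_nodule_params(i, "benign", cfg)$vdt_days, numeric(1))
  expect_true(all(is.na(ben)))
})

test_that("invalid simulator bounds are rejected", {
  expect_error(simulator_config(diameter_range_mm = c(10, 6)), "diameter")
  expect_error(simulator_config(vdt_range_days = c(100, 400)), "vdt")
})

test_that("rendered patches have the specified geometry and bounded values", {
  p <- sample_nodule_params(3, "malignant")
  img <- render_patch(p, 0)
  expect_identical(dim(img), c(64L, 64L))
  expect_equal(attr(img, "pixel_spacing_mm"), 0.5)
  expect_equal(attr(img, "side_mm"), 32)
  expect_true(all(is.finite(img)) && all(img >= 0) && all(img <= 1))
})

test_that("rendered diameter is recovered by an independent area-based scan", {
  cfg <- simulator_config()
  for (i in 1:15) {
    p <- sample_nodule_params(i + 400, "benign", cfg)
    p$margin <- "smooth"; p$spicule_count <- 0L
    p$attenuation <- "solid"; p$peak_intensity <- 0.85
    class(p) <- "nodule_params"
    img <- render_patch(p, 0)
    expect_lt(abs(oracle_diameter(img) - p$diameter_mm), 0.5) # within 1 pixel
  }
})

test_that("benign nodules are exactly stable; noise-free foregrounds match", {
  p <- sample_nodule_params(9, "benign")
  a <- render_patch(p, 0, add_noise = FALSE)
  b <- render_patch(p, 12, add_noise = FALSE)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("diameter growth follows the volume-doubling law with clipping", {
  p <- sample_nodule_params(5, "malignant")
  p$diameter_mm <- 10; p$vdt_days <- 365
  class(p) <- "nodule_params"
  d12 <- diameter_at(p, 12)
  expect_equal(as.numeric(d12), 10 * 2^((365.25) / (3 * 365)), tolerance = 1e-10)
  expect_false(attr(d12, "clipped"))
  d99 <- diameter_at(p, 20 * 12)
  expect_equal(as.numeric(d99), 30)
  expect_true(attr(d99, "clipped"))
})

test_that("generated pairs carry label, interval and reproduce byte-identically", {
  ds1 <- generate_dataset(2, 3, seed = 21)
  ds2 <- generate_dataset(2, 3, seed = 21)
  expect_identical(ds1, ds2)
  expect_length(ds1, 5)
  expect_identical(sum(attr(ds1, "labels") == "malignant"), 2L)
  expect_equal(ds1[[1]]$interval_months, 12)
  expect_identical(ds1[[1]]$label, "malignant")
  expect_error(generate_dataset(-1, 2, seed = 1), "non-negative")
  empty <- generate_dataset(0, 0, seed = 1)
  expect_length(empty, 0)
})

test_that("dataset round-trips through disk in both formats", {
  ds <- generate_dataset(1, 2, seed = 31)
  for (fmt in c("csv", "png")) {
    dir <- tempfile()
    write_nodule_dataset(ds, dir, format = fmt)
    back <- read_nodule_dataset(dir)
    expect_length(back, 3)
    expect_identical(attr(back, "labels"), attr(ds, "labels"))
    tol <- if (fmt == "png") 1 / 255 else 1e-6
    expect_lt(max(abs(unclass(back[[1]]$baseline) -
                        unclass(ds[[1]]$baseline))), tol)
    unlink(dir, recursive = TRUE)
  }
})
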