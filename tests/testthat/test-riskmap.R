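test_that("class linearisation reproduces the printed anchors", {
  plastic <- class_grid(matrix(c(8, 0, 4, NA), 2, 2), n_classes = 8, max_exponent = 6)
  lin <- linearise_classes(plastic, units = "pieces km^-2")
  expect_equal(lin[1, 1], 1e6)
  expect_equal(lin[2, 1], 1)
  expect_equal(lin[1, 2], 10^(6 / 8 * 4))
  expect_true(is.na(lin[2, 2]))
  zoo <- class_grid(matrix(5), n_classes = 5, max_exponent = 2)
  expect_equal(linearise_classes(zoo)[1, 1], 100)
})

test_that("linearisation is strictly increasing and exactly invertible", {
  set.seed(17)
  g <- class_grid(matrix(sample(0:8, 60, TRUE), 6, 10), 8, 6)
  lin <- linearise_classes(g)
  expect_equal((8 / 6) * log10(unclass(lin)), unclass(g),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  seq_vals <- 10^((6 / 8) * 0:8)
  expect_true(all(diff(seq_vals) > 0))
})

test_that("class grids reject out-of-range or fractional values, naming the cell", {
  expect_error(
    class_grid(matrix(c(1, 9), 1, 2), 8, 6),
    "\\[1, 2\\]",
    class = "plastisize_invalid_grid"
  )
  expect_error(class_grid(matrix(2.5), 8, 6), class = "plastisize_invalid_grid")
  expect_error(class_grid(matrix(-1), 8, 6), class = "plastisize_invalid_grid")
})

test_that("the zooplankton community selects the smallest class with a 0.14 mm buffer", {
  sel <- select_ingestible_class(published_fit(), 13.5)
  expect_identical(sel$index, 1L)
  expect_equal(sel$upper_mm, 1.00)
  expect_equal(round(sel$buffer_mm, 2), 0.14)
})

test_that("class upper bounds are closed and selection is monotone", {
  # a flat fit predicting exactly 4.76 mm must select the 1.00-4.76 class
  flat <- plastisize::published_fit()
  flat$slope <- 0
  flat$intercept <- log10(4.76)
  sel <- select_ingestible_class(flat, 50)
  expect_identical(sel$index, 2L)
  expect_equal(sel$buffer_mm, 0)
  # 88.6 mm body -> ~5 mm prediction -> third class
  body5 <- 10^((log10(5) + 1.1200) / 0.9341)
  expect_equal(body5, 88.6, tolerance = 0.001)
  sel5 <- select_ingestible_class(published_fit(), body5)
  expect_identical(sel5$index, 3L)
  expect_equal(sel5$lower_mm, 4.76)
  # monotone in body length
  bodies <- 10^seq(0, 4.5, length.out = 40)
  idx <- vapply(
    bodies,
    function(b) select_ingestible_class(published_fit(), b)$index, 1L
  )
  expect_true(all(diff(idx) >= 0))
})

test_that("selection fails cleanly when no class can hold the prediction", {
  bounded <- size_classes(c(0.33, 1.00), c(1.00, 4.76))
  expect_error(
    select_ingestible_class(published_fit(), 10340, bounded),
    class = "plastisize_no_class"
  )
})

test_that("total_plastic sums cellwise with the any-present mask rule", {
  ones <- concentration_grid(matrix(1, 3, 3), "pieces km^-2")
  four <- total_plastic(list(ones, ones, ones, ones))
  expect_true(all(unclass(four) == 4))
  expect_equal(unclass(total_plastic(list(ones))), unclass(ones))
  # random grids against a cellwise loop oracle
  set.seed(23)
  grids <- lapply(1:4, function(i) {
    v <- matrix(runif(20, 0, 100), 4, 5)
    v[sample(20, 4)] <- NA
    concentration_grid(v, "pieces km^-2")
  })
  got <- total_plastic(grids)
  for (r in 1:4) {
    for (c in 1:5) {
      cell <- vapply(grids, function(g) unclass(g)[r, c], 1.0)
      if (all(is.na(cell))) {
        expect_true(is.na(got[r, c]))
      } else {
        expect_equal(got[r, c], sum(cell, na.rm = TRUE), tolerance = 1e-12)
      }
    }
  }
  expect_error(
    total_plastic(list(ones, concentration_grid(matrix(1, 2, 2), "pieces km^-2"))),
    class = "plastisize_invalid_grid"
  )
  expect_error(
    total_plastic(list(ones, concentration_grid(matrix(1, 3, 3), "mg C m^-3"))),
    class = "plastisize_invalid_grid"
  )
})

test_that("risk_index divides cellwise, masking zero-density cells", {
  plastic <- concentration_grid(
    matrix(c(10, 1000, 100, 0), 2, 2),
    "pieces km^-2"
  )
  zoo <- concentration_grid(matrix(c(1, 0, 10, 100), 2, 2), "mg C m^-3")
  risk <- risk_index(plastic, zoo)
  expect_equal(risk[1, 1], 10)
  expect_equal(risk[1, 2], 10)
  expect_true(is.na(risk[2, 1]))
  expect_equal(risk[2, 2], 0)
  # same positive grid over itself is 1 everywhere
  same <- concentration_grid(matrix(runif(9, 1, 5), 3, 3), "x")
  expect_true(all(unclass(risk_index(same, same)) == 1))
})

test_that("risk_index is homogeneous in each argument", {
  set.seed(29)
  for (i in 1:50) {
    p <- matrix(runif(12, 0, 100), 3, 4)
    z <- matrix(runif(12, 0.1, 10), 3, 4)
    p[sample(12, 2)] <- NA
    k <- runif(1, 0.1, 10)
    pg <- concentration_grid(p, "pieces km^-2")
    zg <- concentration_grid(z, "mg C m^-3")
    base <- unclass(risk_index(pg, zg))
    scaled_p <- unclass(risk_index(concentration_grid(p * k, "pieces km^-2"), zg))
    scaled_z <- unclass(risk_index(pg, concentration_grid(z * k, "mg C m^-3")))
    expect_equal(scaled_p, k * base, tolerance = 1e-12)
    expect_equal(scaled_z, base / k, tolerance = 1e-12)
    # mask conservation: NA pattern of the result never loses a source mask
    expect_true(all(is.na(base)[is.na(p)]))
  }
})

test_that("synthetic grids are reproducible and drive the full pipeline", {
  a <- generate_synthetic_grids(c(12, 24), seed = 3)
  b <- generate_synthetic_grids(c(12, 24), seed = 3)
  expect_identical(a, b)
  expect_length(a$plastic, 4)
  for (g in a$plastic) {
    v <- unclass(g)
    expect_true(all(is.na(v) | (v >= 0 & v <= 8 & v == round(v))))
  }
  zv <- unclass(a$zooplankton)
  expect_true(all(is.na(zv) | (zv >= 0 & zv <= 5)))

  plastic_conc <- lapply(a$plastic, linearise_classes, units = "pieces km^-2")
  zoo_conc <- linearise_classes(a$zooplankton, units = "mg C m^-3")
  sel <- select_ingestible_class(published_fit(), 13.5)
  risk <- risk_index(plastic_conc[[sel$index]], zoo_conc)
  expect_identical(dim(risk), c(12L, 24L))
  expect_true(all(unclass(risk) >= 0, na.rm = TRUE))
  risk_all <- risk_index(total_plastic(plastic_conc), zoo_conc)
  expect_true(all(unclass(risk_all) >= unclass(risk), na.rm = TRUE))
})

test_that("grids and size-class tables round-trip through delimited text", {
  g <- generate_synthetic_grids(c(7, 9), seed = 44)
  path <- withr::local_tempfile(fileext = ".txt")
  write_grid(g$plastic[[1]], path)
  back <- read_grid(path)
  expect_s3_class(back, "class_grid")
  expect_equal(unclass(back), unclass(g$plastic[[1]]), ignore_attr = TRUE)
  expect_identical(attr(back, "n_classes"), attr(g$plastic[[1]], "n_classes"))
  expect_equal(attr(back, "max_exponent"), attr(g$plastic[[1]], "max_exponent"))

  lin <- linearise_classes(g$zooplankton, units = "mg C m^-3")
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_grid(lin, path2)
  back2 <- read_grid(path2)
  expect_s3_class(back2, "concentration_grid")
  expect_equal(unclass(back2), unclass(lin), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(attr(back2, "units"), "mg C m^-3")

  cls_path <- withr::local_tempfile(fileext = ".csv")
  write_size_classes(default_size_classes(), cls_path)
  cls <- read_size_classes(cls_path)
  expect_equal(cls, default_size_classes())
})
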