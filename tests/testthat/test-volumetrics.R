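make_box_mask <- function(dim3 = c(20, 20, 10), spacing = c(3, 3, 6),
                          n_sat = 0L, n_vat = 0L, ...) {
  lab <- array(0L, dim3)
  if (n_sat > 0) lab[seq_len(n_sat)] <- 1L
  if (n_vat > 0) lab[prod(dim3) - seq_len(n_vat) + 1L] <- 2L
  label_mask(lab, spacing, ...)
}

test_that("depot volume is voxel count times voxel volume", {
  m <- make_box_mask(c(20, 20, 10), c(3, 3, 6), n_sat = 1000L)
  expect_equal(depot_volume(m, SAT), 1000 * 54 / 1e6)  # 0.054 L
  expect_equal(depot_volume(m, VAT), 0)
  empty <- make_box_mask()
  expect_equal(depot_volume(empty, SAT), 0)
  expect_error(depot_volume(m, 3), "depot_code")
  expect_error(depot_volume(m, c(1, 2)), "depot_code")
})

test_that("digitized ellipsoid volume matches voxel-count oracle and closed form", {
  ax <- c(60, 80, 90)
  dims <- 2 * ax + 10
  cx <- (dims + 1) / 2
  x <- seq_len(dims[1]) - cx[1]
  y <- seq_len(dims[2]) - cx[2]
  z <- seq_len(dims[3]) - cx[3]
  inside <- outer(outer(x^2 / ax[1]^2, y^2 / ax[2]^2, `+`), z^2 / ax[3]^2,
                  `+`) <= 1
  lab <- array(0L, dims); lab[inside] <- 1L
  m <- label_mask(lab, spacing = c(1, 1, 1))
  brute <- sum(inside) * 1e-6          # voxel-count oracle, 1 mm^3 voxels
  expect_equal(depot_volume(m, SAT), brute)
  analytic <- 4 / 3 * pi * prod(ax) * 1e-6
  expect_lt(abs(depot_volume(m, SAT) - analytic) / analytic, 0.02)
})

test_that("mean PDFF restricts to the depot and flags empty depots", {
  dim3 <- c(6, 6, 6)
  lab <- array(0L, dim3); lab[1:40] <- 1L
  vals <- array(0, dim3); vals[1:40] <- 90
  m <- label_mask(lab); p <- scalar_volume(vals)
  expect_equal(mean_pdff(p, m, SAT), 90)

  vals[1:20] <- 60; vals[21:40] <- 80
  p <- scalar_volume(vals)
  expect_equal(mean_pdff(p, m, SAT), 70)

  expect_warning(res <- mean_pdff(p, m, VAT), class = "adipoquant_empty_depot")
  expect_true(is.na(res))
})

test_that("mean PDFF equals an element-wise loop over masked voxels", {
  set.seed(7)
  dim3 <- c(8, 7, 5)
  lab <- array(sample(0:2, prod(dim3), replace = TRUE), dim3)
  vals <- array(runif(prod(dim3), 0, 100), dim3)
  m <- label_mask(lab); p <- scalar_volume(vals)
  for (code in c(SAT, VAT)) {
    acc <- 0; n <- 0
    for (i in seq_len(dim3[1])) for (j in seq_len(dim3[2]))
      for (k in seq_len(dim3[3]))
        if (lab[i, j, k] == code) { acc <- acc + vals[i, j, k]; n <- n + 1 }
    expect_equal(mean_pdff(p, m, code), acc / n)
  }
})

test_that("apparent lipid volume is the PDFF-weighted voxel sum", {
  dim3 <- c(10, 10, 10)
  lab <- array(0L, dim3); lab[1:500] <- 1L
  vals <- array(0, dim3)

  vals[1:500] <- 80
  p <- scalar_volume(vals, spacing = c(10, 10, 20))  # 2 mm^3 voxels -> 1 L
  m <- label_mask(lab, spacing = c(10, 10, 20))
  vol <- depot_volume(m, SAT)
  expect_equal(apparent_lipid_volume(p, m, SAT), 0.8 * vol)

  vals[] <- 0
  expect_equal(apparent_lipid_volume(scalar_volume(vals, c(10, 10, 20)),
                                     m, SAT), 0)

  vals[1:250] <- 60; vals[251:500] <- 80
  p <- scalar_volume(vals, c(10, 10, 20))
  brute <- sum(vals[lab == 1L] / 100) * 2000 / 1e6
  expect_equal(apparent_lipid_volume(p, m, SAT), brute)
  # 2 L depot, half 60 % / half 80 % -> 1.4 L
  expect_equal(vol, 1)
  expect_equal(apparent_lipid_volume(p, m, SAT), 0.7 * vol)
})

test_that("apparent lipid equals mean PDFF times volume and never exceeds it", {
  set.seed(11)
  for (rep in 1:5) {
    dim3 <- c(9, 8, 7)
    lab <- array(sample(0:2, prod(dim3), replace = TRUE), dim3)
    vals <- array(runif(prod(dim3), 0, 100), dim3)
    m <- label_mask(lab); p <- scalar_volume(vals)
    for (code in c(SAT, VAT)) {
      vol <- depot_volume(m, code)
      lip <- apparent_lipid_volume(p, m, code)
      expect_lte(lip, vol)
      expect_equal(lip, mean_pdff(p, m, code) / 100 * vol,
                   tolerance = 1e-9)
    }
  }
})

test_that("normalized volume and VAT/SAT ratio follow their definitions", {
  expect_equal(normalized_volume(12, 40), 0.3)
  expect_equal(normalized_volume(0, 40), 0)
  expect_equal(normalized_volume(4.0, 15), 4 / 15)  # 0.267 L/cm
  expect_error(normalized_volume(1, 0), "positive")
  expect_error(normalized_volume(1, -3), "positive")

  expect_equal(vat_sat_ratio(10, 5), 0.5)
  expect_equal(vat_sat_ratio(10, 0), 0)
  expect_error(vat_sat_ratio(0, 5), "positive")
})

test_that("volumes scale with spacing^3 and lengths with spacing", {
  lab <- array(0L, c(10, 10, 10)); lab[3:8, 3:8, 3:8] <- 1L
  for (k in c(0.5, 2, 3.7)) {
    m1 <- label_mask(lab, spacing = c(3, 3, 6))
    mk <- label_mask(lab, spacing = k * c(3, 3, 6))
    expect_equal(depot_volume(mk, SAT), k^3 * depot_volume(m1, SAT))
    expect_equal(region_extent(mk)$length_cm,
                 k * region_extent(m1)$length_cm)
  }
})

test_that("containers reject invalid inputs", {
  expect_error(scalar_volume(array(-1, c(2, 2, 2))), "\\[0, 100\\]")
  expect_error(scalar_volume(array(101, c(2, 2, 2))), "\\[0, 100\\]")
  expect_error(scalar_volume(matrix(1, 2, 2)), "3D")
  expect_error(scalar_volume(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(label_mask(array(3L, c(2, 2, 2))), "invalid codes")
  expect_error(label_mask(array(0L, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(label_mask(array(0L, c(2, 2, 2)), cc_axis = 4), "cc_axis")
  # lattice mismatch between map and mask
  p <- scalar_volume(array(50, c(3, 3, 3)))
  m <- label_mask(array(1L, c(3, 3, 4)))
  expect_error(mean_pdff(p, m, SAT), "lattice")
})
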