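test_that("phantom generation is deterministic per seed and seed-sensitive", {
  p1 <- make_phantom(small_phantom_spec(seed = 7))
  p2 <- make_phantom(small_phantom_spec(seed = 7))
  expect_identical(p1$pdff$values, p2$pdff$values)
  expect_identical(p1$mask$labels, p2$mask$labels)
  p3 <- make_phantom(small_phantom_spec(seed = 8))
  expect_false(identical(p1$pdff$values, p3$pdff$values))
  expect_identical(p1$mask$labels, p3$mask$labels)  # geometry is seed-free
})

test_that("zero SAT thickness yields zero SAT in mask and truth", {
  spec <- small_phantom_spec(sat_thickness_mm = c(0, 0, 0))
  ph <- make_phantom(spec)
  expect_equal(depot_volume(ph$mask, SAT), 0)
  expect_equal(ph$truth$volume_L[ph$truth$depot == "sat" &
                                   ph$truth$region == "total"], 0)
  expect_gt(depot_volume(ph$mask, VAT), 0)
})

test_that("truth table is internally consistent", {
  ph <- make_phantom(small_phantom_spec())
  tr <- ph$truth
  for (d in c("sat", "vat")) {
    tot <- tr[tr$depot == d & tr$region == "total", ]
    thirds <- tr[tr$depot == d & tr$region != "total", ]
    expect_equal(sum(thirds$volume_L), tot$volume_L)
    expect_equal(sum(thirds$length_cm), tot$length_cm)
    expect_true(all(tr$apparent_lipid_L[tr$depot == d] <=
                      tr$volume_L[tr$depot == d]))
  }
})

test_that("invalid phantom geometry is rejected", {
  expect_error(small_phantom_spec(sat_thickness_mm = c(70, 10, 10)),
               "torso geometry")
  expect_error(small_phantom_spec(vat_fraction = c(0.5, 1.2, 0.5)),
               "vat_fraction")
  expect_error(phantom_spec(torso_semiaxes = c(400, 120)), "grid")
})

test_that("pipeline recovers default-spec phantom volumes within 2 percent", {
  ph <- make_phantom(phantom_spec(seed = 3))
  s <- summarize_subject(ph$pdff, ph$mask)
  tr <- ph$truth
  get_truth <- function(d, r) tr[tr$depot == d & tr$region == r, ]
  for (d in c("sat", "vat")) {
    ds <- s[[d]]
    expect_gt(ds$volume_L, 2)  # depots are study-scale
    tot <- get_truth(d, "total")
    expect_lt(abs(ds$volume_L - tot$volume_L) / tot$volume_L, 0.02)
    expect_lt(abs(ds$apparent_lipid_L - tot$apparent_lipid_L) /
                tot$apparent_lipid_L, 0.02)
    expect_lt(abs(ds$mean_pdff_pct - tot$mean_pdff_pct), 0.5)
    for (t3 in c("upper", "middle", "lower")) {
      tv <- get_truth(d, t3)
      expect_lt(abs(ds$thirds[[t3]]$volume_L - tv$volume_L) / tv$volume_L,
                0.02)
    }
    # partition conservation (same voxels, no resampling)
    vols <- vapply(ds$thirds, function(x) x$volume_L, numeric(1))
    expect_equal(sum(vols), ds$volume_L, tolerance = 1e-12)
  }
  expect_equal(s$extent$length_cm,
               get_truth("sat", "total")$length_cm)
})

test_that("identity follow-up spec leaves the phantom unchanged", {
  ph <- make_phantom(small_phantom_spec())
  fu <- make_followup(ph, followup_spec(sat_retention = c(1, 1, 1),
                                        vat_retention = c(1, 1, 1),
                                        pdff_shift = c(0, 0)))
  expect_identical(fu$mask$labels, ph$mask$labels)
  expect_equal(fu$pdff$values, ph$pdff$values)
})

test_that("follow-up shrinkage hits per-third retention to one voxel", {
  ph <- make_phantom(small_phantom_spec())
  fs <- followup_spec(sat_retention = c(0.70, 0.85, 0.60),
                      vat_retention = c(0.90, 0.75, 0.80))
  fu <- make_followup(ph, fs)
  base_thirds <- partition_thirds(ph$mask)
  fu_thirds <- partition_thirds(fu$mask)
  targets <- rbind(sat = fs$sat_retention, vat = fs$vat_retention)
  for (code in c(SAT, VAT)) {
    depot <- c("sat", "vat")[code]
    for (t3 in 1:3) {
      n0 <- sum(base_thirds[[t3]]$labels == code)
      n1 <- sum(fu_thirds[[t3]]$labels == code)
      expect_equal(n1, unname(round(targets[depot, t3] * n0)))
    }
  }
})

test_that("a planted total SAT retention reproduces the relative loss", {
  ph <- make_phantom(phantom_spec(seed = 5))
  fu <- make_followup(ph, followup_spec(
    sat_retention = c(0.785, 0.785, 0.785),
    vat_retention = c(1, 1, 1), pdff_shift = c(0, 0)))
  rel <- relative_change(depot_volume(ph$mask, SAT),
                         depot_volume(fu$mask, SAT))
  expect_equal(rel, -21.5, tolerance = 0.01)
})

test_that("follow-up PDFF shift moves the depot means", {
  ph <- make_phantom(small_phantom_spec(seed = 2))
  fu <- make_followup(ph, followup_spec(seed = 2))
  expect_equal(mean_pdff(fu$pdff, fu$mask, SAT),
               mean_pdff(ph$pdff, ph$mask, SAT) - 1.96, tolerance = 0.05)
  expect_equal(mean_pdff(fu$pdff, fu$mask, VAT),
               mean_pdff(ph$pdff, ph$mask, VAT) - 4.18, tolerance = 0.1)
})

test_that("unattainable retention is reported with the offending third", {
  ph <- make_phantom(small_phantom_spec())
  expect_error(make_followup(ph, followup_spec(
    sat_retention = c(1e-6, 1, 1), vat_retention = c(1, 1, 1))),
    "upper")
})
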