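# Shape factors, stress-fiber density, vinculin:actin ratio, nuclei counts.

test_that("segmentation recovers rendered cell geometry within 2%", {
  spec <- synthetic_cell_spec(cell_major_axis = 40, cell_minor_axis = 20,
                              n_fibers = 0, adhesion_count = 0)
  out <- render_cell_image(spec)
  cells <- segment_cells(out$channels$actin, min_area = 100,
                         pixel_size = spec$pixel_size)
  expect_length(cells, 1L)
  expect_equal(cells[[1]]$major_um, 40, tolerance = 0.02)
  expect_equal(cells[[1]]$minor_um, 20, tolerance = 0.02)
  expect_warning(segment_cells(matrix(0, 50, 50)), "flat")
  # two disjoint cells segment into two masks with correct areas
  two <- matrix(0, 60, 120)
  two[10:30, 10:30] <- 1   # 21 x 21 square
  two[10:40, 70:100] <- 1  # 31 x 31 square
  masks <- segment_cells(two, min_area = 50)
  expect_length(masks, 2L)
  expect_setequal(vapply(masks, `[[`, numeric(1), "area_px"),
                  c(21 * 21, 31 * 31))
})

test_that("shape factors: circle 1, 2:1 ellipse 0.5, rotation-invariant", {
  circ <- render_cell_image(synthetic_cell_spec(40, 40, n_fibers = 0,
                                                adhesion_count = 0))
  expect_equal(cell_shape_factor(circ$truth$cell_mask), 1, tolerance = 0.02)
  ell <- render_cell_image(synthetic_cell_spec(40, 20, n_fibers = 0,
                                               adhesion_count = 0))
  expect_equal(cell_shape_factor(ell$truth$cell_mask), 0.5,
               tolerance = 0.02 / 0.5)
  rot <- render_cell_image(synthetic_cell_spec(
    40, 20, cell_orientation = 37 * pi / 180, n_fibers = 0,
    adhesion_count = 0))
  expect_lt(abs(cell_shape_factor(rot$truth$cell_mask) -
                  cell_shape_factor(ell$truth$cell_mask)), 0.01)
})

test_that("nuclear shape factor matches the cell convention and its contract", {
  out <- render_cell_image(synthetic_cell_spec(
    40, 30, nucleus_major_axis = 16, nucleus_minor_axis = 8,
    n_fibers = 0, adhesion_count = 0))
  expect_equal(nuclear_shape_factor(out$truth$nucleus_mask), 0.5,
               tolerance = 0.04)
  circ <- render_cell_image(synthetic_cell_spec(
    40, 40, nucleus_major_axis = 12, nucleus_minor_axis = 12,
    n_fibers = 0, adhesion_count = 0))
  expect_equal(nuclear_shape_factor(circ$truth$nucleus_mask), 1,
               tolerance = 0.02)
  # perimeter-based circularity is also 1 for a circle
  expect_equal(nuclear_shape_factor(circ$truth$nucleus_mask,
                                    method = "circularity"), 1,
               tolerance = 0.1)
  two <- matrix(FALSE, 40, 40)
  two[5:10, 5:10] <- TRUE
  two[25:30, 25:30] <- TRUE
  expect_error(nuclear_shape_factor(two), "exactly one")
})

test_that("stress-fiber factor: zero on uniform actin, recovers rendered coverage", {
  spec0 <- synthetic_cell_spec(n_fibers = 0, adhesion_count = 0)
  out0 <- render_cell_image(spec0)
  expect_equal(stress_fiber_factor(out0$channels$actin,
                                   out0$truth$cell_mask), 0)
  # ~15% fiber coverage, the regime the metric is designed for
  spec <- synthetic_cell_spec(n_fibers = 4, seed = 8, adhesion_count = 0)
  out <- render_cell_image(spec)
  sff <- stress_fiber_factor(out$channels$actin, out$truth$cell_mask,
                             log_sigma_px = spec$fiber_width /
                               spec$pixel_size / 2)
  expect_lt(abs(sff - out$truth$fiber_fraction), 0.03)
  # invariant to uniform intensity scaling
  sff2 <- stress_fiber_factor(out$channels$actin * 7.3,
                              out$truth$cell_mask,
                              log_sigma_px = 2)
  sff1 <- stress_fiber_factor(out$channels$actin, out$truth$cell_mask,
                              log_sigma_px = 2)
  expect_equal(sff1, sff2, tolerance = 1e-12)
})

test_that("the same fibers in a doubled cell area halve the factor", {
  h <- w <- 240
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  small <- ((X - 120) / 70)^2 + ((Y - 120) / 35)^2 <= 1
  big <- ((X - 120) / 99)^2 + ((Y - 120) / 49.5)^2 <= 1  # ~2x area
  fibers <- (abs(Y - 110) <= 2 | abs(Y - 130) <= 2) & small
  mk <- function(mask) {
    img <- matrix(0.01, h, w)
    img[mask] <- 0.2
    img[fibers] <- 1
    img
  }
  f_small <- stress_fiber_factor(mk(small), small, log_sigma_px = 2)
  f_big <- stress_fiber_factor(mk(big), big, log_sigma_px = 2)
  expect_equal(f_big / f_small, sum(small) / sum(big), tolerance = 0.25)
})

test_that("stress-fiber factor is monotone in true fiber coverage", {
  vals <- vapply(c(2, 5, 9), function(nf) {
    out <- render_cell_image(synthetic_cell_spec(n_fibers = nf, seed = 21,
                                                 adhesion_count = 0))
    c(stress_fiber_factor(out$channels$actin, out$truth$cell_mask,
                          log_sigma_px = 2), out$truth$fiber_fraction)
  }, numeric(2))
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) > 0))
})

test_that("vinculin:actin ratio obeys identity, zero and linearity", {
  out <- render_cell_image(synthetic_cell_spec(seed = 9))
  m <- out$truth$cell_mask
  actin <- out$channels$actin
  expect_equal(vinculin_actin_ratio(actin, actin, m), 1)
  expect_equal(vinculin_actin_ratio(actin * 0, actin, m), 0)
  vinc <- out$channels$vinculin
  r1 <- vinculin_actin_ratio(vinc, actin, m)
  expect_equal(vinculin_actin_ratio(vinc / 2, actin, m), r1 / 2,
               tolerance = 1e-12)
  expect_error(vinculin_actin_ratio(vinc, actin * 0, m), "zero")
})

test_that("nuclei counting is exact on rendered separated fields", {
  expect_equal(count_nuclei(matrix(0, 64, 64)), 0L)
  for (n in c(5, 25)) {
    f <- render_nuclei_field(n, seed = n)
    expect_equal(count_nuclei(f$image), n)
  }
  batch <- lapply(1:9, function(i) render_nuclei_field(10, seed = i)$image)
  res <- count_nuclei_batch(batch)
  expect_equal(res$mean_count, 10)
  expect_equal(res$n_fields, 9L)
})

test_that("watershed splitting separates touching nuclei", {
  img <- matrix(0, 60, 60)
  # two overlapping discs
  for (c0 in list(c(25, 30), c(37, 30))) {
    X <- matrix(rep(0:59, each = 60), 60, 60)
    Y <- matrix(rep(0:59, times = 60), 60, 60)
    img[(X - c0[1])^2 + (Y - c0[2])^2 <= 49] <- 1
  }
  expect_equal(count_nuclei(img, min_area = 20, split_touching = FALSE), 1L)
  expect_equal(count_nuclei(img, min_area = 20, split_touching = TRUE), 2L)
})

test_that("ROI polygons build masks matching rendered geometry", {
  # a diamond (rotated square) with diagonals 40 and 20 px
  verts <- data.frame(x = c(30, 50, 30, 10), y = c(10, 30, 50, 30))
  mask <- roi_to_mask(verts, dim = c(60, 60))
  expect_equal(mask$area_px, 800, tolerance = 0.05)
  expect_equal(cell_shape_factor(mask), 1, tolerance = 0.03)
})

test_that("max projection collapses stacks by per-pixel maximum", {
  st <- array(0, dim = c(4, 4, 3))
  st[1, 1, 2] <- 5
  st[4, 4, 1] <- 2
  mp <- max_project(st)
  expect_equal(mp[1, 1], 5)
  expect_equal(mp[4, 4], 2)
  expect_equal(max_project(list(st[, , 1], st[, , 2], st[, , 3])), mp)
})
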