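# Image-quantification primitives: flatfield, background, segmentation,
# rings, regions, FISH counting and round registration.

disk_image <- function(dim, centres, radius, intensity = 500, bg = 10) {
  img <- matrix(bg, dim[1], dim[2])
  for (i in seq_len(nrow(centres))) {
    d2 <- outer((seq_len(dim[1]) - centres[i, 2])^2,
                (seq_len(dim[2]) - centres[i, 1])^2, "+")
    img[d2 <= radius^2] <- intensity
  }
  img
}

test_that("flatfield correction normalizes the bias to mean 1", {
  img <- matrix(runif(100 * 100, 50, 150), 100)
  expect_equal(flatfield_correct(img, matrix(3, 100, 100)), img)
  # piecewise bias: left half 2, right half 1 (mean 1.5 after normalization)
  bias <- cbind(matrix(2, 100, 50), matrix(1, 100, 50))
  out <- flatfield_correct(img, bias)
  expect_equal(out[, 1:50], img[, 1:50] * 0.75)
  expect_equal(out[, 51:100], img[, 51:100] * 1.5)
  expect_error(flatfield_correct(img, -bias), "positive")
  expect_error(flatfield_correct(img, bias[1:50, ]), "dimensions")
})

test_that("local background subtraction removes smooth backgrounds only", {
  expect_true(all(subtract_background_local(matrix(7, 200, 200)) == 0))
  # ramp background plus sparse bright spots: spot amplitudes preserved
  nr <- 256
  ramp <- outer(seq(0, 50, length.out = nr), seq(0, 50, length.out = nr),
                "+") / 2
  img <- ramp
  set.seed(5)
  pos <- cbind(sample(20:236, 25), sample(20:236, 25))
  img[pos] <- img[pos] + 400
  out <- subtract_background_local(img, 64)
  expect_true(all(abs(out[pos] - 400) / 400 < 0.05))
  # an already background-free sparse image passes through (percentile bias)
  sparse <- matrix(0, 256, 256); sparse[pos] <- 400
  out2 <- subtract_background_local(sparse, 64)
  expect_equal(out2[pos], rep(400, 25))
  # block larger than image: global percentile fallback
  small <- matrix(5, 40, 40); small[20, 20] <- 100
  out3 <- subtract_background_local(small, 64)
  expect_equal(out3[20, 20], 95)
  expect_error(subtract_background_local(small, 16), ">= 32")
})

test_that("segmentation finds separated and touching disks", {
  expect_equal(max(segment_nuclei(matrix(3, 128, 128))), 0)
  # two disks three radii apart
  img <- disk_image(c(128, 128), rbind(c(40, 64), c(88, 64)), radius = 8)
  m <- segment_nuclei(img)
  expect_equal(max(m), 2)
  cents <- attr(m, "centroids")
  ref <- rbind(c(40, 64), c(88, 64))
  err <- sqrt(rowSums((cents[order(cents[, "x"]), ] - ref)^2))
  expect_true(all(err < 1))
  # overlapping disks (centre distance 1.8 R) split by the watershed
  img2 <- disk_image(c(128, 128), rbind(c(56, 64), c(70.4, 64)), radius = 8)
  m2 <- segment_nuclei(img2)
  expect_equal(max(m2), 2)
})

test_that("cytoplasmic rings have analytic area and stay disjoint", {
  px <- 0.65
  img <- disk_image(c(200, 200), cbind(100, 100), radius = 12)
  m <- segment_nuclei(img)
  ring <- cytoplasm_ring(m, px)
  # analytic annulus between R+inner and R+outer around a circular nucleus
  R <- sqrt(attr(m, "areas") / pi)
  expected <- pi * ((R + 3.25 / px)^2 - (R + 0.65 / px)^2)
  expect_lt(abs(sum(ring == 1) - expected) / expected, 0.10)
  expect_equal(sum(ring > 0 & m > 0), 0)       # disjoint from the nucleus
  # two nuclei 1 um apart: rings never overlap by construction
  img2 <- disk_image(c(200, 200), rbind(c(80, 100), c(80 + 24 + 1 / px, 100)),
                     radius = 12)
  m2 <- segment_nuclei(img2)
  ring2 <- cytoplasm_ring(m2, px)
  expect_equal(max(m2), 2)
  owners <- unique(ring2[ring2 > 0])
  expect_setequal(owners, 1:2)
  # pixels cannot belong to two rings in a label image, so check the
  # boundary rule instead: every ring pixel is nearest its own nucleus
  expect_equal(sum(ring2 > 0 & m2 > 0), 0)
  # degenerate radii produce an empty ring and a missing-value record
  ring0 <- cytoplasm_ring(m, px, inner_um = 2, outer_um = 2)
  expect_equal(sum(ring0 > 0), 0)
  act <- cdk2_activity(img, m, ring0)
  expect_true(is.na(act$cdk2_activity))
  expect_equal(act$reason, "empty_ring")
})

test_that("whole-cell regions partition their union by nearest nucleus", {
  px <- 0.65
  img <- disk_image(c(256, 256), rbind(c(90, 128), c(170, 128)), radius = 10)
  m <- segment_nuclei(img)
  reg <- whole_cell_region(m, px)
  # regions cover both nuclei and nothing overlaps (label image partition)
  expect_true(all(reg[m > 0] == m[m > 0]))
  expect_equal(sum(reg > 0), sum(reg == 1) + sum(reg == 2))
  # the boundary between the two regions is the equidistant line (here the
  # vertical midline between the centres at x = 130)
  cents <- attr(m, "centroids")
  left <- which.min(cents[, "x"])
  idx <- which(reg == left, arr.ind = TRUE)
  expect_true(all(idx[, 2] <= 130))
  idxr <- which(reg == (3 - left), arr.ind = TRUE)
  expect_true(all(idxr[, 2] >= 130))
  # single nucleus: region is the 15.6 um dilation
  img1 <- disk_image(c(256, 256), cbind(128, 128), radius = 10)
  m1 <- segment_nuclei(img1)
  reg1 <- whole_cell_region(m1, px)
  d <- as.matrix(EBImage::distmap(EBImage::Image((m1 == 0) * 1)))
  expect_true(all((d[reg1 == 1 & m1 == 0]) <= 15.6 / px))
  expect_true(all(reg1[m1 == 0 & d > 0 & d <= 15.6 / px] == 1))
})

test_that("activity ratio is scale invariant and flags empty compartments", {
  img <- disk_image(c(128, 128), cbind(64, 64), radius = 10, intensity = 300,
                    bg = 0)
  m <- segment_nuclei(img + 10)
  ring <- cytoplasm_ring(m, 0.65)
  uniform <- matrix(50, 128, 128)
  expect_equal(cdk2_activity(uniform, m, ring)$cdk2_activity, 1)
  rep2 <- img; rep2[ring == 1] <- 600
  a1 <- cdk2_activity(rep2, m, ring)$cdk2_activity
  a2 <- cdk2_activity(rep2 * 13, m, ring)$cdk2_activity
  expect_equal(a1, 2)
  expect_equal(a1, a2)
  zero <- matrix(0, 128, 128); zero[ring == 1] <- 5
  expect_equal(cdk2_activity(zero, m, ring)$reason, "zero_nuclear_mean")
})

test_that("FISH counting is exact on blanks and sublinear under crowding", {
  region <- matrix(1L, 256, 256)
  blank <- matrix(0, 256, 256)
  expect_equal(count_fish_pixels(blank, region, 0.65,
                                 abs_threshold = 10)$puncta_pixels, 0L)
  expect_error(count_fish_pixels(blank, region, 0.65, abs_threshold = 0),
               "> 0")
  expect_error(count_fish_pixels(blank, region, 10, abs_threshold = 5),
               "below 1 px")
  # crowding: per-spot pixel yield decreases as spots overlap
  cfg <- sim_config(seed = 9)
  sparse <- place_spots(20, c(256, 256), min_sep = 16, seed = 9)
  set.seed(9)
  dense <- data.frame(x = sample(10:246, 3000, replace = TRUE),
                      y = sample(10:246, 3000, replace = TRUE),
                      amplitude = 200, sigma_px = 1.2)
  empty_cells <- data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
                            nucleus_radius_px = numeric(0),
                            cyto_radius_px = numeric(0),
                            nuclear_intensity = numeric(0),
                            cdk2_activity = numeric(0))
  f_sparse <- render_frames(empty_cells, cfg, c(256, 256), spots = sparse,
                            psf = FALSE)
  f_dense <- render_frames(empty_cells, cfg, c(256, 256), spots = dense,
                           psf = FALSE)
  c_sparse <- count_fish_pixels(f_sparse$channels$fish, region, 0.65,
                                abs_threshold = 40)$puncta_pixels / 20
  c_dense <- count_fish_pixels(f_dense$channels$fish, region, 0.65,
                               abs_threshold = 40)$puncta_pixels / 3000
  expect_lt(c_dense, c_sparse)
})

test_that("round registration recovers planted integer shifts", {
  set.seed(14)
  base <- matrix(runif(128 * 128), 128)
  base <- as.matrix(EBImage::gblur(base, 1))
  same <- register_rounds(base, base)
  expect_equal(unname(same$shift), c(0, 0))
  expect_true(same$ok)
  shift_img <- function(img, dy, dx) {
    out <- matrix(0, nrow(img), ncol(img))
    ys <- seq_len(nrow(img) - abs(dy)); xs <- seq_len(ncol(img) - abs(dx))
    out[ys + max(dy, 0), xs + max(dx, 0)] <-
      img[ys - min(dy, 0), xs - min(dx, 0)]
    out
  }
  mov <- shift_img(base, 5, -3)
  res <- register_rounds(base, mov)
  expect_equal(unname(res$shift), c(-5, 3))
  # and mapping centroids with that shift aligns them back
  cent_fixed <- matrix(c(60, 40), 1, dimnames = list(NULL, c("x", "y")))
  cent_live <- cent_fixed
  cent_fixed[1, ] <- cent_fixed[1, ] + c(-3, 5)  # moved like the image
  mm <- match_rounds(cent_live, cent_fixed, shift = res$shift)
  expect_equal(mm$fixed, 1L)
  expect_lt(mm$distance, 1e-9)
  # 10% noise: exact integer recovery in 19 of 20 seeds or better
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    noisy <- mov + matrix(rnorm(128 * 128, 0, 0.1 * sd(base)), 128)
    r <- register_rounds(base, noisy)
    if (all(r$shift == c(-5, 3))) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("quantified noiseless frames recover the planted measurements", {
  cfg <- sim_config(seed = 33)
  cells <- place_cells(12, c(512, 512), cfg,
                       cdk2_activities = c(0.5, 1, 2))
  fr <- render_frames(cells, cfg, c(512, 512))
  q <- quantify_frame(fr$channels, cfg$pixel_size_um)
  expect_equal(max(q$mask), nrow(cells))
  truth_cent <- as.matrix(cells[, c("x", "y")])
  colnames(truth_cent) <- c("x", "y")
  m <- match_rounds(attr(q$mask, "centroids"), truth_cent, max_dist = 3)
  expect_true(all(!is.na(m$fixed)))
  err <- abs(q$records$cdk2_activity - cells$cdk2_activity[m$fixed]) /
    cells$cdk2_activity[m$fixed]
  expect_lt(max(err), 0.02)
  # ring/nucleus disjointness on the frame
  expect_equal(sum(q$ring > 0 & q$mask > 0), 0)
})
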