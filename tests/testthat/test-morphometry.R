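box_volume <- function(dims = c(30, 30, 30), disc_dim = c(10, 40, 20)) {
  # axis-aligned box disc with a centred box NP; used where exactness under
  # cube morphology is required
  dims <- pmax(dims, disc_dim + 8)
  vol <- array(10, dims)
  ctr <- round(dims / 2)
  disc <- array(FALSE, dims)
  dz <- (disc_dim[1] - 1) %/% 2; dy <- (disc_dim[2] - 1) %/% 2
  dx <- (disc_dim[3] - 1) %/% 2
  disc[(ctr[1] - dz):(ctr[1] + disc_dim[1] - 1 - dz),
       (ctr[2] - dy):(ctr[2] + disc_dim[2] - 1 - dy),
       (ctr[3] - dx):(ctr[3] + disc_dim[3] - 1 - dx)] <- TRUE
  np <- array(FALSE, dims)
  npd <- pmax(disc_dim %/% 3, 3)
  nz <- (npd[1] - 1) %/% 2; ny <- (npd[2] - 1) %/% 2; nx <- (npd[3] - 1) %/% 2
  np[(ctr[1] - nz):(ctr[1] + npd[1] - 1 - nz),
     (ctr[2] - ny):(ctr[2] + npd[2] - 1 - ny),
     (ctr[3] - nx):(ctr[3] + npd[3] - 1 - nx)] <- TRUE
  vol[disc] <- 100
  vol[np] <- 200
  list(vol = disc_volume(vol, 10), masks = mask_set(disc = disc, np = np))
}

test_that("Gaussian smoothing preserves constants, identity and mass", {
  const <- disc_volume(array(42, c(10, 10, 10)), 10)
  expect_equal(smooth_volume(const)$data, const$data, tolerance = 1e-12)

  withr::with_seed(3, {
    rnd <- disc_volume(array(runif(1000), c(10, 10, 10)), 10)
    expect_identical(smooth_volume(rnd, kernel = 1)$data, rnd$data)
  })

  spark <- array(0, c(15, 15, 15))
  spark[8, 8, 8] <- 1000  # interior voxel: total intensity conserved
  sm <- smooth_volume(disc_volume(spark, 10))
  expect_equal(sum(sm$data), 1000, tolerance = 1e-6)
  expect_error(smooth_volume(const, kernel = 2), class = "ivdnet_bad_kernel")
})

test_that("disc mask interpolates contours by signed distance", {
  circle <- function(r, ctr = c(16, 16), n = 64) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
  }
  # identical circles on slices 1 and 11 -> a cylinder across 1..11
  cyl <- build_disc_mask(contour_set(list(`1` = circle(10), `11` = circle(10))),
                         c(12, 32, 32))
  areas <- apply(cyl$disc, 1, sum)
  expect_true(all(areas[1:11] == areas[1]))
  expect_equal(areas[12], 0)  # outside the contoured span: empty

  # radius 10 at slice 1, radius 20 at slice 11 -> radius ~15 at slice 6
  cone <- build_disc_mask(contour_set(list(`1` = circle(5, c(24, 24)),
                                           `11` = circle(15, c(24, 24)))),
                          c(12, 48, 48))
  mid_area <- sum(cone$disc[6, , ])
  r_mid <- sqrt(mid_area / pi)
  expect_lt(abs(r_mid - 10), 1)  # +/- 1 voxel rasterization tolerance

  # areas are monotone between slices when the endpoint areas are ordered
  withr::with_seed(17, {
    for (i in 1:10) {
      r0 <- runif(1, 4, 9); r1 <- runif(1, 10, 18)
      m <- build_disc_mask(contour_set(list(`1` = circle(r0, c(24, 24)),
                                            `11` = circle(r1, c(24, 24)))),
                           c(11, 48, 48))
      a <- apply(m$disc, 1, sum)
      expect_true(all(diff(a) >= 0))
    }
  })

  expect_error(build_disc_mask(contour_set(list(`1` = circle(5), `40` = circle(5))),
                               c(12, 32, 32)),
               class = "ivdnet_bad_contours")
  expect_error(contour_set(list(`1` = circle(5))), class = "ivdnet_bad_contours")
})

test_that("NP segmentation recovers planted regions", {
  # box NP: exact end-to-end equality (boxes are invariant under 3^3 close/open)
  bx <- box_volume()
  seg <- segment_np(bx$vol, bx$masks$disc)
  expect_identical(seg$np, bx$masks$np)

  # ellipsoid phantom, noise-free: threshold candidate is exact; the full
  # morphological pipeline agrees on > 99.5% of NP voxels
  spec <- small_phantom_spec()
  ph <- generate_disc_volume(spec, seed = 1)
  inside <- ph$volume$data[ph$masks$disc]
  thr <- ivdnet:::otsu_threshold(inside)
  cand <- ph$volume$data >= thr & ph$masks$disc
  expect_identical(cand, ph$masks$np)
  seg2 <- segment_np(ph$volume, ph$masks$disc)
  agreement <- sum(seg2$np & ph$masks$np) / sum(seg2$np | ph$masks$np)
  expect_gt(agreement, 0.98)
  npvf_seg <- sum(seg2$np) / sum(ph$masks$disc)
  npvf_truth <- sum(ph$masks$np) / sum(ph$masks$disc)
  expect_equal(npvf_seg, npvf_truth, tolerance = 0.02)

  # determinism
  seg3 <- segment_np(ph$volume, ph$masks$disc)
  expect_identical(seg2$np, seg3$np)

  expect_error(segment_np(ph$volume, array(FALSE, dim(ph$volume$data))),
               class = "ivdnet_empty_mask")
  expect_error(segment_np(ph$volume, ph$masks$disc, threshold = 1e6),
               class = "ivdnet_bad_threshold")
})

test_that("morphological close fills holes; largest component removes specks", {
  bx <- box_volume()
  holed <- bx$vol
  ctr <- round(dim(holed$data) / 2)
  holed$data[ctr[1], ctr[2], ctr[3]] <- 100  # 1-voxel interior hole in the NP
  seg <- segment_np(holed, bx$masks$disc)
  expect_true(seg$np[ctr[1], ctr[2], ctr[3]])  # hole filled by close

  specked <- bx$vol
  # a bright 2x2x2 blob in the annulus, away from the NP
  idx <- which(bx$masks$disc & !bx$masks$np, arr.ind = TRUE)
  corner <- idx[which.max(rowSums(idx)), ]
  specked$data[corner[1] - 1:0, corner[2] - 1:0, corner[3] - 1:0] <- 200
  seg2 <- segment_np(specked, bx$masks$disc)
  expect_false(seg2$np[corner[1], corner[2], corner[3]])  # speck dropped
  expect_identical(seg2$np, bx$masks$np)
})

test_that("morphometry metrics match construction and are rescale-invariant", {
  bx <- box_volume()
  m <- morphometry_metrics(bx$vol, bx$masks)
  expect_equal(m$npvf, sum(bx$masks$np) / sum(bx$masks$disc))
  expect_equal(m$dhi, 10 / 40)  # box 10 tall x 40 wide on every central slice

  # NIDI at equal volumes of NP (200) and non-NP disc (100): 200/150 = 4/3
  dims <- c(20, 20, 20)
  vol <- array(10, dims)
  disc <- array(FALSE, dims); disc[5:14, 5:14, 3:12] <- TRUE
  np <- array(FALSE, dims); np[5:14, 5:14, 3:7] <- TRUE  # exactly half the disc
  vol[disc] <- 100; vol[np] <- 200
  m2 <- morphometry_metrics(disc_volume(vol, 10), mask_set(disc = disc, np = np))
  expect_equal(m2$nidi, 4 / 3)

  # NPVF invariant under monotone intensity rescaling at fixed masks
  resc <- disc_volume(sqrt(bx$vol$data) * 7 + 3, 10)
  expect_equal(morphometry_metrics(resc, bx$masks)$npvf, m$npvf)

  thin <- mask_set(disc = array(rep(c(TRUE, rep(FALSE, 19)), 400), c(20, 20, 20)),
                   np = array(FALSE, c(20, 20, 20)))
  expect_error(morphometry_metrics(bx$vol, mask_set(bx$masks$disc,
                                                    array(FALSE, dim(bx$vol$data)))),
               class = "ivdnet_empty_mask")
})

test_that("full pipeline recovers planted NPVF and NIDI on phantoms", {
  spec <- small_phantom_spec(np_semiaxes = c(9, 11, 11))
  ph <- generate_disc_volume(spec, seed = 2)
  res <- morphometry_pipeline(ph$volume, phantom_contours(spec))
  truth_npvf <- sum(ph$masks$np) / sum(ph$masks$disc)
  truth_nidi <- mean(ph$volume$data[ph$masks$np]) /
    mean(ph$volume$data[ph$masks$disc])
  expect_equal(res$metrics$npvf, truth_npvf, tolerance = 0.02)
  expect_equal(res$metrics$nidi, truth_nidi, tolerance = 0.01)
})
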