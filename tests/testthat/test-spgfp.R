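# Core quantification pipeline: projection, foreground segmentation, cell
# splitting, mitochondrial masking, per-cell statistics.

test_that("sum projection matches an explicit per-pixel loop exactly", {
  set.seed(1)
  a <- array(sample.int(65535, 5 * 24 * 16, replace = TRUE),
             dim = c(5, 24, 16))
  st <- ImageStack(list(gfp = a))
  expect_identical(sumProject(st, "gfp"), loopSumProject(a))
  # trivial cases
  one <- array(c(1, 2, 3), dim = c(3, 1, 1))
  expect_equal(sumProject(ImageStack(list(gfp = one)), "gfp")[1, 1], 6)
  z <- array(0, dim = c(4, 3, 3))
  expect_true(all(sumProject(ImageStack(list(gfp = z)), "gfp") == 0))
  expect_error(sumProject(st, "dapi"), "unknown channel")
})

test_that("no overflow for full-range 16-bit stacks", {
  a <- array(65535, dim = c(40, 8, 8))
  expect_equal(sumProject(ImageStack(list(gfp = a)), "gfp")[1, 1], 40 * 65535)
})

test_that("two-plateau image is segmented into exact plateau membership", {
  img <- matrix(10, 40, 40)
  img[10:25, 12:28] <- 1000
  mask <- segmentForeground(img, smoothRadius = 0)
  expect_equal(mask, img == 1000, ignore_attr = TRUE)
})

test_that("foreground seeds retain their labels in the output", {
  f <- smallField(seed = 9, noiseSd = 2, shot = TRUE)
  proj <- sumProject(f$stack, "gfp") + sumProject(f$stack, "mcherry")
  sm <- mitoSpGFP:::.medianSmooth(proj, 2)
  qs <- quantile(sm, c(0.2, 0.95), names = FALSE)
  mask <- segmentForeground(proj)
  expect_true(all(mask[sm >= qs[2] & sm > qs[1]]))
  expect_true(all(!mask[sm <= qs[1]]))
})

test_that("constant image yields an all-background mask with a warning", {
  expect_warning(m <- segmentForeground(matrix(7, 20, 20)), "constant")
  expect_true(all(!m))
  expect_true(attr(m, "degenerate"))
})

test_that("cell splitting matches the geodesic nearest-marker oracle", {
  # two radius-10 disks fused by a 4-pixel neck
  mask <- matrix(FALSE, 50, 60)
  for (y in 1:50) for (x in 1:60) {
    if ((y - 25)^2 + (x - 18)^2 <= 100) mask[y, x] <- TRUE
    if ((y - 25)^2 + (x - 42)^2 <= 100) mask[y, x] <- TRUE
  }
  mask[24:27, 28:32] <- TRUE  # the neck
  lab <- splitCells(mask, minArea = 20)
  expect_identical(max(lab), 2L)
  markers <- attr(lab, "markers")
  expect_identical(nrow(markers), 2L)
  oracle <- bfsLabels(mask, markers)
  expect_equal(lab, oracle, ignore_attr = TRUE)
  # the split runs near the neck: each disk centre keeps its own label
  expect_false(lab[25, 18] == lab[25, 42])

  # one isolated blob -> one label
  blob <- matrix(FALSE, 30, 30)
  blob[8:22, 8:22] <- TRUE
  expect_identical(max(splitCells(blob, minArea = 20)), 1L)

  # empty mask -> zero cells, not an error
  empty <- splitCells(matrix(FALSE, 10, 10))
  expect_identical(max(empty), 0L)
})

test_that("small components are removed and border labels are excluded", {
  mask <- matrix(FALSE, 40, 40)
  mask[5:20, 5:20] <- TRUE     # interior cell
  mask[30:32, 30:32] <- TRUE   # 9-pixel speck
  mask[1:10, 35:40] <- TRUE    # touches the border
  lab <- splitCells(mask, minArea = 20)
  expect_identical(max(lab), 1L)
  lab2 <- splitCells(mask, minArea = 20, excludeBorder = FALSE)
  expect_identical(max(lab2), 2L)
  expect_true(any(attr(lab2, "borderTouching")))
})

test_that("mitochondrial masking uses an inclusive per-cell threshold", {
  m <- matrix(c(9, 10, 11, 200), 2, 2)
  mask <- mitoMask(m, matrix(TRUE, 2, 2), fraction = 0.05)
  expect_equal(attr(mask, "threshold"), 10)
  expect_identical(as.vector(mask), c(FALSE, TRUE, TRUE, TRUE))

  # uniform positive marker -> whole cell
  u <- matrix(5, 4, 4)
  expect_true(all(mitoMask(u, matrix(TRUE, 4, 4))))

  # all-zero marker -> empty mask with qc flag
  z <- mitoMask(matrix(0, 4, 4), matrix(TRUE, 4, 4))
  expect_true(attr(z, "qcEmpty"))
  expect_true(all(!z))
  expect_error(mitoMask(u, matrix(FALSE, 4, 4)), "empty")

  # random cells: exact agreement with the per-pixel loop oracle
  set.seed(42)
  for (r in 1:5) {
    mch <- matrix(runif(64 * 64, 0, 300), 64, 64)
    cell <- matrix(runif(64 * 64) < 0.3, 64, 64)
    cell[1, 1] <- TRUE
    got <- mitoMask(mch, cell, fraction = 0.05)
    expect_equal(got, loopMitoMask(mch, cell, 0.05), ignore_attr = TRUE)
  }
})

test_that("the per-cell maximum is per cell, not per image", {
  mch <- matrix(0, 10, 20)
  cellA <- matrix(FALSE, 10, 20); cellA[3:8, 2:8] <- TRUE
  cellB <- matrix(FALSE, 10, 20); cellB[3:8, 12:18] <- TRUE
  mch[cellA] <- 10   # dim cell
  mch[cellB] <- 1000 # bright cell
  mA <- mitoMask(mch, cellA, fraction = 0.05)
  expect_true(all(mA[cellA]))  # threshold 0.5, not 50
})

test_that("per-cell medians and ratios follow the stated conventions", {
  expect_equal(sortMedian(c(1, 2, 3, 4)), 2.5)
  expect_equal(median(c(1, 2, 3, 4)), 2.5)

  f <- smallField(seed = 5)
  q <- quantifyCells(f$stack)
  ok <- q$cells$qc_flags == ""
  expect_true(all(q$cells$mito_area[ok] <= q$cells$cell_area[ok]))
  expect_equal(q$cells$mito_threshold, 0.05 * q$cells$mcherry_max)
  expect_equal(q$cells$spgfp_ratio[ok],
               q$cells$spgfp_median[ok] / q$cells$mcherry_median[ok])

  # GFP uniform over the mito mask -> median equals that value
  lab <- q$labels
  gfp <- sumProject(f$stack, "gfp")
  expect_true(all(q$cells$spgfp_median[ok] == 85))
})

test_that("containment holds pixelwise: mito in cell in foreground", {
  f <- smallField(seed = 13, noiseSd = 1, shot = TRUE)
  gfp <- sumProject(f$stack, "gfp")
  mch <- sumProject(f$stack, "mcherry")
  fg <- segmentForeground(gfp + mch)
  lab <- splitCells(fg)
  expect_true(all(fg[lab > 0]))
  for (i in seq_len(max(lab))) {
    mm <- mitoMask(mch, lab == i)
    expect_true(all((lab == i)[mm]))
  }
})

test_that("ratios are scale invariant and medians scale equivariantly", {
  f <- smallField(seed = 5)
  q0 <- quantifyCells(f$stack)
  scaleStack <- function(st, gf, mf) {
    ImageStack(list(gfp = getChannel(st, "gfp") * gf,
                    mcherry = getChannel(st, "mcherry") * mf),
               pixelSize = st@pixelSize, zStep = st@zStep)
  }
  q3 <- quantifyCells(scaleStack(f$stack, 3, 3))
  expect_equal(q3$cells$spgfp_ratio, q0$cells$spgfp_ratio, tolerance = 1e-12)
  qg <- quantifyCells(scaleStack(f$stack, 3, 1))
  expect_equal(qg$cells$spgfp_median, 3 * q0$cells$spgfp_median,
               tolerance = 1e-12)
  # mito mask invariant under marker rescaling
  mch <- sumProject(f$stack, "mcherry")
  cell <- q0$labels == 1
  expect_equal(mitoMask(mch * 7.3, cell), mitoMask(mch, cell),
               ignore_attr = TRUE)
})

test_that("masking can fall back to the image-wide maximum when asked", {
  f <- smallField(seed = 5, nCells = 4)
  qPer <- quantifyCells(f$stack)
  qImg <- quantifyCells(f$stack, perImageMax = TRUE)
  expect_identical(nrow(qPer$cells), nrow(qImg$cells))
  expect_true(all(qImg$cells$mito_threshold ==
                    0.05 * max(qImg$cells$mcherry_max)))
})
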