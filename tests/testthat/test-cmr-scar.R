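# CMR scar module: normalisation, classification, wall splitting,
# projection and quantification.

test_that("normalisation applies the remote z formula and guards degeneracy", {
  vol <- LGEVolume(array(100, c(6, 6, 2)), c(1, 1, 1))
  ii <- intensities(vol)
  ii[1, 1, 1] <- 130
  vol <- LGEVolume(ii, c(1, 1, 1))
  wall <- array(TRUE, c(6, 6, 2))
  masks <- list(wall = wall, endoHalf = wall, epiHalf = array(FALSE, dim(wall)))
  zv <- normalizeToSDUnits(vol, c(100, 10), masks)
  expect_equal(zValues(zv)[1, 1, 1], 3.0)
  expect_equal(zValues(zv)[2, 2, 1], 0)
  # constant ROI -> degenerate
  roi <- array(FALSE, dim(wall)); roi[, , 2] <- TRUE
  expect_error(normalizeToSDUnits(vol, roi, masks), "degenerate")
  # too-small ROI
  roi2 <- array(FALSE, dim(wall)); roi2[1:3, 1, 1] <- TRUE
  expect_error(normalizeToSDUnits(vol, roi2, masks), "30 voxels")
})

test_that("tissue classification matches the 2/3 SD thresholds", {
  expect_equal(as.character(classifyTissue(c(1.99, 2, 2.5, 2.999, 3, 5))),
               c("HM", "HT", "HT", "HT", "DS", "DS"))
  expect_error(classifyTissue(c(1, NA)), "finite")
  expect_error(classifyTissue(Inf), "finite")
})

test_that("wall halves split at the mid-wall with the endo tie rule", {
  spec <- smallCMRSpec(scar = FALSE, endoRadius = 20, epiRadius = 30,
                       gridShape = c(64L, 64L, 2L), voxelSize = c(1, 1, 5))
  g <- generateCMR(spec)
  masks <- splitWallHalves(g$contours, g$volume)
  d <- dim(intensities(g$volume))
  cx <- (seq_len(d[1]) - 0.5) - d[1] / 2
  R <- sqrt(outer(cx^2, cx^2, "+"))
  pick <- function(r) {
    i <- which(abs(R - r) == min(abs(R - r)), arr.ind = TRUE)[1, ]
    c(endo = masks$endoHalf[i[1], i[2], 1], epi = masks$epiHalf[i[1], i[2], 1])
  }
  expect_true(pick(22)[["endo"]])
  expect_true(pick(28)[["epi"]])
  # partition is exact
  expect_identical(masks$endoHalf | masks$epiHalf, masks$wall)
  expect_false(any(masks$endoHalf & masks$epiHalf))
})

test_that("equidistant voxels take the endocardial half by the tie rule", {
  # rectangular contours: voxel centre (24.5, 15.5) is exactly 4.5 mm from
  # both the endo edge (x = 20) and the epi edge (x = 29)
  rect <- function(x0, x1, y0, y1, surface)
    data.frame(slice = 0L, surface = surface,
               x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  ct <- WallContours(rbind(rect(10, 20, 10, 20, "endo"),
                           rect(5, 29, 5, 29, "epi")))
  vol <- LGEVolume(array(1, c(34L, 34L, 1L)), c(1, 1, 5))
  masks <- splitWallHalves(ct, vol)
  expect_true(masks$wall[25, 16, 1])
  expect_true(masks$endoHalf[25, 16, 1])
  expect_false(masks$epiHalf[25, 16, 1])
})

test_that("uniform z projects to uniform node SI and labels", {
  # epi-half at exactly 2.5 SD everywhere -> every epi node is HT at 2.5
  spec <- smallCMRSpec(offset = 2.5, span = 360, slices = 0:5, noiseSD = 0)
  ch <- runCMRChain(spec)
  m <- ch$mapEp
  on <- m@mapped
  expect_true(all(abs(nodeSI(m)[on] - 2.5) < 1e-9))
  expect_true(all(tissueLabels(m)[on] == "HT"))
  # null case: no scar -> all HM, zero HT/DS areas
  ch0 <- runCMRChain(smallCMRSpec(scar = FALSE))
  expect_true(all(tissueLabels(ch0$mapEp)[ch0$mapEp@mapped] == "HM"))
  expect_equal(ch0$quant@epHT, 0)
  expect_equal(ch0$quant@epDS, 0)
})

test_that("compartment areas, masses and volumes are quantified", {
  spec <- smallCMRSpec()
  ch <- runCMRChain(spec)
  m <- ch$mapEp
  byHand <- sum(nodeAreas(m)[m@mapped & tissueLabels(m) == "DS"])
  expect_equal(ch$quant@epDS, byHand)
  # disjoint label partition: per-label areas sum to the mapped area
  tot <- sum(nodeAreas(m)[m@mapped])
  parts <- sum(tapply(nodeAreas(m)[m@mapped], tissueLabels(m)[m@mapped], sum),
               na.rm = TRUE)
  expect_equal(parts, tot)
  # masses: voxel-level z >= 2 times 1.05 g/ml
  z <- zValues(ch$z)
  scarMl <- sum(ch$z@wall & !is.na(z) & z >= 2) * prod(voxelSize(ch$z)) / 1000
  expect_equal(ch$quant@tsm, scarMl * 1.05)
  expect_gt(ch$quant@tmm, ch$quant@tsm)
})

test_that("Simpson slice summation recovers a cylinder volume", {
  # 8 circular endo slices of r = 10 mm and 8 mm thickness: ~20.1 ml
  ang <- 2 * pi * (0:143) / 144
  cc <- do.call(rbind, lapply(0:7, function(s) rbind(
    data.frame(slice = s, surface = "endo", x = 30 + 10 * cos(ang),
               y = 30 + 10 * sin(ang)),
    data.frame(slice = s, surface = "epi", x = 30 + 15 * cos(ang),
               y = 30 + 15 * sin(ang)))))
  ct <- WallContours(cc)
  spec <- smallCMRSpec(scar = FALSE, voxelSize = c(1.3, 1.3, 8))
  ch <- runCMRChain(spec)
  q <- quantifyScar(ch$mapEn, ch$mapEp, ch$z, edContours = ct,
                    esContours = ct)
  expect_equal(q@lvedv, pi * 100 * 8 * 8 / 1000, tolerance = 0.005)
  expect_equal(q@lvef, 0)                    # identical phases
})

test_that("percentage change follows the baseline-relative definition", {
  expect_equal(percentChange(10, 15), 50)
  expect_equal(percentChange(8, 8), 0)
  expect_equal(percentChange(20, 15), -25)
  expect_error(percentChange(0, 5), "zero baseline")
})

test_that("labels and areas are invariant under affine intensity rescaling", {
  spec <- smallCMRSpec(noiseSD = 10, seed = 21L)
  g <- generateCMR(spec)
  masks <- splitWallHalves(g$contours, g$volume)
  roi <- g$remoteROI
  z1 <- normalizeToSDUnits(g$volume, roi, masks)
  vol2 <- LGEVolume(3.7 * intensities(g$volume) + 55, voxelSize(g$volume))
  z2 <- normalizeToSDUnits(vol2, roi, masks)
  expect_equal(zValues(z1), zValues(z2), tolerance = 1e-9)
  dz <- spec@voxelSize[3]
  mesh <- contourSurfaceMesh(g$contours, "epi", dz)
  m1 <- projectHalfWallSI(z1, "epi", mesh)
  m2 <- projectHalfWallSI(z2, "epi", mesh)
  expect_identical(as.character(tissueLabels(m1)),
                   as.character(tissueLabels(m2)))
})

test_that("raising scar offsets never shrinks DS nor grows HM", {
  areas <- lapply(c(3.2, 4.5, 6), function(off) {
    ch <- runCMRChain(smallCMRSpec(offset = off))
    m <- ch$mapEp
    list(ds = ch$quant@epDS,
         hm = sum(nodeAreas(m)[m@mapped & tissueLabels(m) == "HM"]))
  })
  ds <- vapply(areas, `[[`, numeric(1), "ds")
  hm <- vapply(areas, `[[`, numeric(1), "hm")
  expect_true(all(diff(ds) >= 0))
  expect_true(all(diff(hm) <= 0))
})

test_that("noiseless phantom areas match the analytic sector area", {
  spec <- syntheticCMRSpec(gridShape = c(64L, 64L, 8L),
                           scarRegions = list(list(angleStart = 0,
                                                   angleSpan = 90,
                                                   slices = 1:6,
                                                   compartment = "epi-half",
                                                   offset = 4)),
                           noiseSD = 0, nContourVertices = 120L, seed = 3L)
  ch <- runCMRChain(spec)
  analytic <- 90 / 360 * 2 * pi * 26 * 5 * 6 / 100     # cm^2
  expect_lt(abs(ch$quant@epDS - analytic) / analytic, 0.05)
})
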