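# Electroanatomic mapping: IDW interpolation, amplitude classes, areas.

test_that("node classification follows the 0.5/1.5 mV and 5 mm rules", {
  # tiny two-triangle mesh in a plane
  mesh <- TriangleMesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                             c(10, 10, 0)),
                       rbind(c(1, 2, 3), c(2, 4, 3)))
  pts <- data.frame(x = c(1, 9), y = c(1, 1), z = c(0, 0),
                    amplitude = c(0.3, 1.5))
  st <- EAMStudy(pts, mesh, fillThreshold = 5)
  vm <- interpolateVoltage(st)
  cls <- as.character(nodeClasses(vm))
  expect_equal(cls[1], "DS")          # 0.3 mV point within 5 mm
  expect_equal(cls[2], "HT")          # exactly 1.5 mV is heterogeneous
  expect_equal(cls[3], "unmapped")    # nearest point > 5 mm away
  expect_error(interpolateVoltage(EAMStudy(pts[0, ], mesh, 5)),
               "empty point set")
})

test_that("class areas sum triangles with the majority/fractional rule", {
  mesh <- TriangleMesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                             c(10, 10, 0)),
                       rbind(c(1, 2, 3), c(2, 4, 3)))
  # all nodes DS: both triangles DS; total 1 cm^2
  cls <- factor(rep("DS", 4), levels = c("DS", "HT", "healthy", "unmapped"))
  a <- epiScarMap:::computeClassAreas(mesh, cls)
  expect_equal(a[["DS"]], 1.0)
  expect_equal(sum(a), 1.0)
  # three distinct classes on a triangle: one third each
  cls2 <- factor(c("DS", "HT", "healthy", "healthy"),
                 levels = c("DS", "HT", "healthy", "unmapped"))
  a2 <- epiScarMap:::computeClassAreas(mesh, cls2)
  expect_equal(a2[["DS"]], 0.5 / 3)
  expect_equal(sum(a2), 1.0)
})

test_that("no low-voltage nodes means zero scar areas", {
  g <- generateEAM(syntheticEAMSpec(seed = 8L))       # no patches
  vm <- interpolateVoltage(g$study)
  expect_equal(classAreas(vm)[["DS"]], 0)
  expect_equal(classAreas(vm)[["HT"]], 0)
})

test_that("a dense-sampled DS patch is recovered within one triangle", {
  spec <- syntheticEAMSpec(pointSpacing = 2,
                           scarPatches = list(list(center = c(0, 60),
                                                   radius = 25,
                                                   class = "DS")),
                           seed = 2L)
  g <- generateEAM(spec)
  vm <- interpolateVoltage(g$study)
  maxTri <- max(epiScarMap:::triangleAreas(meshNodes(g$study@mesh),
                                           meshTriangles(g$study@mesh))) / 100
  expect_lte(abs(classAreas(vm)[["DS"]] - g$truthAreas[["DS"]]), maxTri)
  # area conservation over mapped classes
  a <- classAreas(vm)
  tot <- sum(epiScarMap:::triangleAreas(meshNodes(g$study@mesh),
                                        meshTriangles(g$study@mesh))) / 100
  expect_equal(sum(a), tot, tolerance = 1e-9)
})

test_that("mesh refinement changes class areas by less than 2%", {
  spec <- syntheticEAMSpec(mesh = lvCapMesh(nTheta = 48L, nPhi = 20L),
                           pointSpacing = 2.5,
                           scarPatches = list(list(center = c(0, 60),
                                                   radius = 30,
                                                   class = "DS")),
                           seed = 5L)
  g <- generateEAM(spec)
  vm <- interpolateVoltage(g$study)
  fine <- EAMStudy(g$study@points, subdivideMesh(g$study@mesh),
                   fillThreshold = g$study@fillThreshold)
  vmF <- interpolateVoltage(fine)
  total <- sum(classAreas(vm))
  for (cl in c("DS", "healthy"))
    expect_lt(abs(classAreas(vmF)[[cl]] - classAreas(vm)[[cl]]) / total,
              0.02)
})
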