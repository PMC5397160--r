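test_that("axis distances are plain Euclidean distances between anchor CAs", {
  # anchors: motif0 at origin, Zn anchor at (3,4,0) -> axis1 = 5;
  # motifIa at origin, motif IV at (0,0,5) -> axis2 = 5
  s <- caStructure(resno = c(34, 79, 268, 420),
                   xyz = rbind(c(0, 0, 0), c(0, 0, 0),
                               c(0, 0, 5), c(3, 4, 0)))
  cc <- conformationalCoordinates(s, referenceAnchors(structureId(s)))
  expect_equal(cc$axis1, 5)
  expect_equal(cc$axis2, 5)
})

test_that("conformational coordinates are invariant under global rigid motion", {
  fam <- makeHingeFamily(angles = 40, seed = 30)
  s <- fam$structures[[1]]
  anch <- fam$anchors
  cc0 <- conformationalCoordinates(s, anch, chain = "A")
  set.seed(31)
  for (i in 1:100) {
    s2 <- transformStructure(s, randomRotation(), rnorm(3, sd = 50))
    cc <- conformationalCoordinates(s2, anch, chain = "A")
    expect_equal(cc$axis1, cc0$axis1, tolerance = 1e-9)
    expect_equal(cc$axis2, cc0$axis2, tolerance = 1e-9)
  }
})

test_that("pipeline coordinates equal the generator's analytic distances", {
  fam <- makeHingeFamily(angles = c(0, 30), seed = 32)
  for (k in 1:2) {
    cc1 <- conformationalCoordinates(fam$structures[[k]], fam$anchors,
                                     pairing = "cross1", chain = "A")
    cc2 <- conformationalCoordinates(fam$structures[[k]], fam$anchors,
                                     pairing = "cross2", chain = "A")
    expect_equal(cc1$axis1, fam$truth$axis1_cross1[k], tolerance = 1e-9)
    expect_equal(cc1$axis2, fam$truth$axis2_cross1[k], tolerance = 1e-9)
    expect_equal(cc2$axis1, fam$truth$axis1_cross2[k], tolerance = 1e-9)
    expect_equal(cc2$axis2, fam$truth$axis2_cross2[k], tolerance = 1e-9)
  }
})

test_that("cross-domain axis distances grow monotonically with hinge angle", {
  fam <- makeHingeFamily(angles = seq(0, 90, by = 10), seed = 33)
  tab <- buildLandscape(fam$structures)
  expect_true(all(diff(tab$axis1) > 0))
  expect_true(all(diff(tab$axis2) > 0))
})

test_that("the landscape table has one deterministic row per chain", {
  fam <- makeHingeFamily(angles = 25, seed = 34,
                         nucleotideStates = "ADP")
  tab <- buildLandscape(fam$structures)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$nucleotide_state, "ADP")
  expect_equal(nrow(attr(tab, "skipped")), 0)
  expect_error(buildLandscape(list()), "no structures")
})

test_that("chains with unresolvable anchors are skipped with a warning", {
  famGood <- makeHingeFamily(angles = 10, seed = 35)
  famBad <- makeHingeFamily(angles = 10, seed = 35,
                            missing = list(c(420, 420)))
  expect_warning(
    tab <- buildLandscape(c(famGood$structures, famBad$structures)),
    "unmappable-anchor")
  expect_equal(nrow(tab), 1)
  expect_equal(nrow(attr(tab, "skipped")), 1)
})

test_that("two hinge families separate into two clusters of three", {
  fam <- makeHingeFamily(angles = c(15, 15, 15, 75, 75, 75), noiseSd = 0.3,
                         seed = 36, nucleotideStates = "ADP")
  tab <- buildLandscape(fam$structures)
  expect_equal(nrow(tab), 6)
  st <- classifyStates(tab, k = 2, seed = 0)
  truthOpen <- fam$truth$angle[match(st$structure_id,
                                     fam$truth$structure_id)] > 45
  expect_equal(st$label == "open", truthOpen)
  expect_equal(unname(table(st$label)["open"]), 3)
})

test_that("threshold classification agrees with k-means on separated groups", {
  fam <- makeHingeFamily(angles = c(15, 15, 15, 75, 75, 75), noiseSd = 0.3,
                         seed = 37)
  tab <- buildLandscape(fam$structures)
  km <- classifyStates(tab, method = "kmeans", k = 2, seed = 0)
  cut <- mean(range(tab$axis1))
  th <- classifyStates(tab, method = "threshold", cutoff = cut)
  expect_equal(km$label, th$label)
})

test_that("degenerate classification inputs raise a parameter error", {
  fam <- makeHingeFamily(angles = c(20, 20), seed = 38)
  tab <- buildLandscape(fam$structures)
  expect_error(classifyStates(tab, k = 2), "parameter error")
  expect_error(classifyStates(tab, method = "threshold"), "cutoff")
})

test_that("k = 3 labels an intermediate group between open and closed", {
  fam <- makeHingeFamily(angles = c(5, 5, 45, 45, 100, 100), noiseSd = 0.2,
                         seed = 39)
  tab <- buildLandscape(fam$structures)
  st <- classifyStates(tab, k = 3, seed = 0)
  byAngle <- fam$truth$angle[match(st$structure_id,
                                   fam$truth$structure_id)]
  expect_true(all(st$label[byAngle == 5] == "closed"))
  expect_true(all(st$label[byAngle == 45] == "intermediate"))
  expect_true(all(st$label[byAngle == 100] == "open"))
})

test_that("the landscape plot builds without error", {
  fam <- makeHingeFamily(angles = c(10, 80), seed = 40,
                         nucleotideStates = c("APO", "ADP"))
  tab <- buildLandscape(fam$structures)
  p <- plotLandscape(tab)
  expect_s3_class(p, "ggplot")
})
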