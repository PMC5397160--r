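test_that("superposing a structure onto itself gives the identity transform", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  s <- kabschSuperpose(P, P)
  expect_equal(rotation(s), diag(3), tolerance = 1e-10)
  expect_equal(translation(s), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(rmsd(s), 0, tolerance = 1e-10)
})

test_that("a known rotation + translation is recovered exactly", {
  set.seed(2)
  P <- matrix(rnorm(30), 10, 3)
  R <- rotationMatrix(c(0, 0, 1), 90)
  tr <- c(5, 0, 0)
  Q <- transformCoordinates(P, R, tr)
  s <- kabschSuperpose(P, Q)
  expect_equal(rotation(s), R, tolerance = 1e-9)
  expect_equal(translation(s), tr, tolerance = 1e-9)
  expect_lt(rmsd(s), 1e-9)
  # applying the recovered transform reproduces the reference
  expect_equal(transformCoordinates(P, s), Q, tolerance = 1e-9)
})

test_that("Kabsch beats random rigid transforms on noisy data", {
  set.seed(3)
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  Q <- transformCoordinates(P, randomRotation(), rnorm(3)) +
    matrix(rnorm(30, sd = 0.1), 10, 3)
  s <- kabschSuperpose(P, Q)
  expect_gte(rmsd(s), 0)
  expect_lte(rmsd(s), 0.3)
  rmsdUnder <- function(R, tr) {
    fitted <- transformCoordinates(P, R, tr)
    sqrt(mean(rowSums((fitted - Q)^2)))
  }
  worstCase <- min(replicate(1000, rmsdUnder(randomRotation(),
                                             rnorm(3, sd = 2))))
  expect_lte(rmsd(s), worstCase + 1e-12)
})

test_that("every superposition returns a proper rotation", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    P <- matrix(rnorm(3 * n, sd = 4), n, 3)
    Q <- matrix(rnorm(3 * n, sd = 4), n, 3)
    s <- kabschSuperpose(P, Q)
    R <- rotation(s)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
  }
})

test_that("degenerate inputs are rejected", {
  P <- matrix(rnorm(6), 2, 3)
  expect_error(kabschSuperpose(P, P), "degenerate-superposition")
  line <- cbind(1:5, 2 * (1:5), -(1:5))   # collinear
  expect_error(kabschSuperpose(line, line), "degenerate-superposition")
})

test_that("identical structures give an all-zero displacement profile", {
  fam <- makeHingeFamily(angles = 40, seed = 5)
  s <- fam$structures[[1]]
  dp <- displacementProfile(s, s)
  expect_equal(maxDisplacement(dp), 0, tolerance = 1e-10)
  expect_true(all(profileTable(dp)$displacement < 1e-10))
})

test_that("hinge displacement follows the chord-length law at several angles", {
  base <- makeHingeFamily(angles = 0, seed = 6)
  for (theta in c(10, 30, 60)) {
    fam <- makeHingeFamily(angles = c(0, theta), seed = 6)
    dp <- displacementProfile(fam$structures[[1]], fam$structures[[2]],
                              frame = domainDefinition("D1"))
    expected <- fam$truth$max_displacement_from_base[2]
    expect_equal(maxDisplacement(dp), expected, tolerance = 1e-6)
    expect_equal(expected, 2 * fam$truth$r_max[2] * sin(theta * pi / 360),
                 tolerance = 1e-12)
  }
})

test_that("displacement profiles are invariant to global rigid motion of both inputs", {
  fam <- makeHingeFamily(angles = c(0, 35), noiseSd = 0.2, seed = 7)
  a <- fam$structures[[1]]; b <- fam$structures[[2]]
  dp0 <- displacementProfile(a, b)
  set.seed(8)
  for (i in 1:5) {
    R <- randomRotation(); tr <- rnorm(3, sd = 30)
    dp1 <- displacementProfile(transformStructure(a, R, tr),
                               transformStructure(b, R, tr))
    expect_equal(profileTable(dp1)$displacement,
                 profileTable(dp0)$displacement, tolerance = 1e-7)
  }
})

test_that("pairwise RMSD matrix is symmetric, zero-diagonal and frame-aware", {
  fam <- makeHingeFamily(angles = c(0, 50), seed = 9)
  s <- fam$structures[[1]]
  # duplicated structure -> zero matrix
  m0 <- pairwiseRMSDMatrix(list(s, s, s))
  expect_equal(m0, matrix(0, 3, 3, dimnames = dimnames(m0)),
               tolerance = 1e-10)
  # global rigid motion is invisible to any frame
  s2 <- transformStructure(s, randomRotation(), c(10, -4, 2))
  m1 <- pairwiseRMSDMatrix(list(s, s2), frame = domainDefinition("D2"))
  expect_lt(max(m1), 1e-9)
  # hinge states share an identical D1: frame-D1 RMSD reflects noise only
  famN <- makeHingeFamily(angles = c(0, 50), noiseSd = 0.1, seed = 10)
  m2 <- pairwiseRMSDMatrix(famN$structures, frame = domainDefinition("D1"))
  expect_lt(m2[1, 2], 1e-9)   # noise is applied to the mobile domain only
  expect_equal(m2, t(m2))
})

test_that("profiles and transforms export to TSV/JSON", {
  fam <- makeHingeFamily(angles = c(0, 20), seed = 12)
  dp <- displacementProfile(fam$structures[[1]], fam$structures[[2]])
  tsv <- tempfile(fileext = ".tsv")
  exportProfile(dp, tsv)
  back <- read.delim(tsv)
  expect_equal(back$displacement_A, profileTable(dp)$displacement)
  js <- tempfile(fileext = ".json")
  exportTransform(dp@superposition, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(matrix(parsed$rotation, 3, 3, byrow = TRUE),
               rotation(dp@superposition), tolerance = 1e-12)
})
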