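test_that("sequences are extracted with residue-number indices", {
  p <- writePDBLines(c(
    pdbAtomLine(1, "CA ", "ALA", "A", 10, 0, 0, 0),
    pdbAtomLine(2, "CA ", "GLY", "A", 11, 3, 0, 0),
    pdbAtomLine(3, "CA ", "TRP", "A", 15, 6, 0, 0)))
  sq <- sequenceFromStructure(readStructure(p))
  expect_equal(sq$sequence, "AGW")
  expect_equal(sq$resno, c(10L, 11L, 15L))   # numbering gap preserved
})

test_that("selenomethionine reads as M and unknown residues as X", {
  p <- writePDBLines(c(
    pdbAtomLine(1, "CA ", "ALA", "A", 1, 0, 0, 0),
    sub("^ATOM  ", "HETATM", pdbAtomLine(2, "CA ", "MSE", "A", 2, 3, 0, 0)),
    pdbAtomLine(3, "CA ", "XYZ", "A", 3, 6, 0, 0)))
  sq <- sequenceFromStructure(readStructure(p))
  expect_equal(sq$sequence, "AMX")
})

test_that("a chain of only waters has no sequence", {
  p <- writePDBLines(
    sub("^ATOM  ", "HETATM", pdbAtomLine(1, "O  ", "HOH", "A", 1,
                                         0, 0, 0, element = "O")))
  expect_error(sequenceFromStructure(readStructure(p)), "empty-sequence")
})

test_that("identical sequences align to the identity mapping with the diagonal score", {
  set.seed(20)
  sq <- randomAASequence(10)
  m <- globalAlign(sq, sq)
  p <- mappingTable(m)
  expect_equal(p$refPos, 1:10)
  expect_equal(p$targetPos, 1:10)
  letters1 <- strsplit(sq, "")[[1]]
  expect_equal(alignmentScore(m),
               sum(vapply(letters1, function(ch) blosum62[ch, ch],
                          numeric(1))))
  expect_equal(percentIdentity(m), 100)
})

test_that("a single deletion shifts the mapping by -1 after the deleted column", {
  m <- globalAlign("ACDEFG", "ACEFG")
  p <- mappingTable(m)
  expect_equal(p$refPos, c(1, 2, 4, 5, 6))
  expect_equal(p$targetPos, c(1, 2, 3, 4, 5))
})

test_that("self-alignment score bounds the score against any other sequence", {
  set.seed(21)
  for (i in 1:5) {
    sq <- randomAASequence(12)
    other <- paste(rev(strsplit(sq, "")[[1]]), collapse = "")
    expect_lte(alignmentScore(globalAlign(sq, other)),
               alignmentScore(globalAlign(sq, sq)))
  }
})

test_that("alignment scores match the exhaustive-enumeration oracle", {
  set.seed(22)
  alpha <- c("A", "C", "G", "T")
  cases <- expand.grid(la = 1:6, lb = 1:6)
  cases <- rbind(cases, data.frame(la = c(7, 8, 8), lb = c(8, 7, 8)))
  for (i in seq_len(nrow(cases))) {
    a <- paste(sample(alpha, cases$la[i], replace = TRUE), collapse = "")
    b <- paste(sample(alpha, cases$lb[i], replace = TRUE), collapse = "")
    expect_equal(alignmentScore(globalAlign(a, b)),
                 enumerateAlignmentScore(a, b, blosum62),
                 tolerance = 1e-9,
                 info = paste(a, "vs", b))
  }
})

test_that("mappings are strictly monotonic in both numberings", {
  set.seed(23)
  for (i in 1:20) {
    a <- randomAASequence(sample(5:60, 1))
    b <- randomAASequence(sample(5:60, 1))
    p <- mappingTable(globalAlign(a, b))
    if (nrow(p) > 1) {
      expect_true(all(diff(p$refPos) > 0))
      expect_true(all(diff(p$targetPos) > 0))
    }
  }
})

test_that("anchors survive a self-mapping unchanged", {
  fam <- makeHingeFamily(angles = 0, seed = 24)
  s <- fam$structures[[1]]
  sq <- sequenceFromStructure(s)
  m <- globalAlign(sq, sq)
  mapped <- mapAnchors(referenceAnchors(), m, s)
  expect_equal(anchors(mapped), anchors(referenceAnchors()))
})

test_that("an insertion before the D2 anchors shifts them while D1 anchors stay", {
  fam <- makeHingeFamily(angles = 0, seed = 25)
  s <- fam$structures[[1]]
  refSq <- sequenceFromStructure(s)
  hom <- makeHomologSequence(refSq$sequence,
                             list(list(type = "ins", pos = 100,
                                       seq = "GGGGG")))
  # build a homolog structure carrying the edited sequence/numbering:
  # alignment of reference vs edited sequence must shift targets >= 100 by 5
  m <- globalAlign(refSq$sequence, hom$sequence)
  p <- mappingTable(m)
  expect_equal(p$targetPos[p$refPos == 34], 34)
  expect_equal(p$targetPos[p$refPos == 79], 79)
  expect_equal(p$targetPos[p$refPos == 268], 273)
  expect_equal(p$targetPos[p$refPos == 420], 425)
  # and the alignment recovers the generator's exact correspondence
  expect_equal(p[, c("refPos", "targetPos")], hom$mapping,
               ignore_attr = TRUE)
})

test_that("a deleted anchor column raises an unmappable-anchor error", {
  fam <- makeHingeFamily(angles = 0, seed = 26)
  s <- fam$structures[[1]]
  refSq <- sequenceFromStructure(s)
  hom <- makeHomologSequence(refSq$sequence,
                             list(list(type = "del", pos = 268,
                                       length = 1)))
  m <- globalAlign(refSq$sequence, hom$sequence)
  expect_error(mapAnchors(referenceAnchors(), m, s), "unmappable-anchor")
})

test_that("alignment recovers nearly all true pairs at 10% substitutions", {
  fracs <- vapply(1:10, function(sd) {
    set.seed(sd + 100)
    ref <- randomAASequence(400)
    hom <- makeHomologSequence(ref, substitutionRate = 0.10,
                               seed = sd + 100)
    p <- mappingTable(globalAlign(ref, hom$sequence))
    truth <- hom$mapping
    hits <- merge(p[, c("refPos", "targetPos")], truth,
                  by = c("refPos", "targetPos"))
    nrow(hits) / nrow(truth)
  }, numeric(1))
  expect_gte(mean(fracs), 0.99)
})
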