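test_that("the axis-outside test is strict beyond the inclusive cutoff", {
  far <- toyStructure(list("A:1" = c(10, 0, 0), "A:2" = c(12, 3, 5)))
  expect_true(axisOutsideProtein(far, zAxis()))
  near <- toyStructure(list("A:1" = c(3, 0, 0)))
  expect_false(axisOutsideProtein(near, zAxis()))
  boundary <- toyStructure(list("A:1" = c(5.5, 0, 0)))
  expect_false(axisOutsideProtein(boundary, zAxis()))  # within is inclusive
  expect_error(new("ProteinStructure",
                   atoms = far@atoms[0, , drop = FALSE], label = "x"),
               "no atoms")
})

test_that("the outside test is covariant under a common rigid transform", {
  set.seed(12)
  s <- toyStructure(list("A:1" = c(8, 1, 2), "A:2" = c(7, -2, 0),
                         "A:3" = c(4.2, 1, 3)))
  ax <- zAxis()
  u <- c(1, 2, 3); u <- u / sqrt(sum(u^2))
  R <- hingeShear:::rotationMatrix(u, 73)
  shift <- c(5, -3, 11)
  s2 <- s
  s2@atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(s@atoms[, c("x", "y", "z")]) %*% t(R), 2, shift, "+")
  ax2 <- ScrewAxis(as.numeric(R %*% ax@point) + shift,
                   as.numeric(R %*% ax@direction), ax@angle)
  expect_equal(axisOutsideProtein(s2, ax2), axisOutsideProtein(s, ax))
  d1 <- hingeShear:::pointLineDistance(
    as.matrix(s@atoms[, c("x", "y", "z")]), ax@point, ax@direction)
  d2 <- hingeShear:::pointLineDistance(
    as.matrix(s2@atoms[, c("x", "y", "z")]), ax2@point, ax2@direction)
  expect_equal(d2, d1, tolerance = 1e-10)
})

test_that("bending residues group into contiguous regions per chain", {
  spec <- DomainSpec("A:1", "B:1",
                     bending = c("A:10", "A:11", "A:12", "A:50", "A:51",
                                 "B:10"))
  regions <- bendingRegions(spec)
  expect_equal(length(regions), 3L)
  expect_true(any(vapply(regions, function(r)
    setequal(r, c("A:10", "A:11", "A:12")), NA)))
})

test_that("mechanical hinges require a C-alpha within the cutoff", {
  s <- toyStructure(list("A:1" = c(100, 0, 0), "B:1" = c(104, 0, 0),
                         "A:10" = c(4, 0, 0),      # bending, CA at 4 A
                         "A:50" = c(40, 0, 0)))    # bending, remote
  spec <- DomainSpec("A:1", "B:1", bending = c("A:10", "A:50"))
  mh <- mechanicalHinges(s, spec, zAxis())
  expect_equal(length(mh), 1L)
  expect_equal(mh[[1]], "A:10")
  aa <- analyzeAxis(s, spec, zAxis())
  expect_true(aa@hasEffectiveHingeAxis)
  # only the CA atom counts: a near side-chain atom does not qualify
  s2 <- toyStructure(list("A:1" = c(100, 0, 0), "B:1" = c(104, 0, 0),
                          "A:10" = c(7, 0, 0)))
  s2 <- addAtoms(s2, "A:10", c(3, 0, 0), elety = "CB")
  spec10 <- DomainSpec("A:1", "B:1", bending = "A:10")
  expect_equal(length(mechanicalHinges(s2, spec10, zAxis())), 0L)
  # bending residue without a CA is skipped with a warning
  s3 <- toyStructure(list("A:1" = c(100, 0, 0), "B:1" = c(104, 0, 0)))
  s3 <- addAtoms(s3, "A:10", c(3, 0, 0), elety = "CB")
  expect_warning(mh3 <- mechanicalHinges(s3, spec10, zAxis()),
                 "without C-alpha")
  expect_equal(length(mh3), 0L)
})

test_that("both bending regions remote means no effective hinge axis", {
  s <- toyStructure(list("A:1" = c(100, 0, 0), "B:1" = c(104, 0, 0),
                         "A:10" = c(40, 0, 0), "A:50" = c(60, 0, 0)))
  spec <- DomainSpec("A:1", "B:1", bending = c("A:10", "A:50"))
  aa <- analyzeAxis(s, spec, zAxis())
  expect_equal(length(aa@mechanicalHinges), 0L)
  expect_false(aa@hasEffectiveHingeAxis)
})

test_that("pitch is |translation|/angle and flip-invariant; zero angle errors", {
  expect_equal(pitch(ScrewAxis(c(0, 0, 0), c(0, 0, 1), 10, 1)), 0.1)
  expect_equal(pitch(ScrewAxis(c(0, 0, 0), c(0, 0, 1), 10, 0)), 0)
  expect_error(pitch(ScrewAxis(c(0, 0, 0), c(0, 0, 1), 0, 1)), "undefined")
  flipped <- ScrewAxis(c(0, 0, 0), c(0, 0, -1), 10, -1)
  expect_equal(pitch(flipped), 0.1)
})

test_that("percentage closure above 50 means closure, otherwise twist", {
  expect_equal(motionType(ScrewAxis(c(0, 0, 0), c(0, 0, 1), 10,
                                    percentClosure = 84)), "closure")
  expect_equal(motionType(ScrewAxis(c(0, 0, 0), c(0, 0, 1), 10,
                                    percentClosure = 50)), "twist")
  expect_equal(motionType(ScrewAxis(c(0, 0, 0), c(0, 0, 1), 10,
                                    percentClosure = 12)), "twist")
})

test_that("the axis-analysis report serializes every field", {
  s <- toyStructure(list("A:1" = c(10, 0, 0), "B:1" = c(14, 0, 0)))
  aa <- analyzeAxis(s, DomainSpec("A:1", "B:1"),
                    ScrewAxis(c(0, 0, 0), c(0, 0, 1), 20, 2,
                              percentClosure = 70))
  path <- withr::local_tempfile()
  writeAxisAnalysis(aa, path)
  txt <- readLines(path)
  expect_true(any(grepl("^pitch_A_per_deg 0.1$", txt)))
  expect_true(any(grepl("^motion_type closure$", txt)))
})
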