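test_that("heavy atoms are kept and hydrogens dropped at parse time", {
  path <- withr::local_tempfile(fileext = ".pdb")
  df <- rbind(pdbRow(1, "N", "A", 1, 0, 0, 0, "N"),
              pdbRow(2, "CA", "A", 1, 1.5, 0, 0, "C"),
              pdbRow(3, "HA", "A", 1, 1.5, 1, 0, "H"),
              pdbRow(4, "CA", "A", 2, 5, 0, 0, "C"),
              pdbRow(5, "HB2", "A", 2, 5, 1, 0, "H"),
              pdbRow(6, "CA", "A", 3, 9, 0, 0, "C"))
  writeMiniPdb(df, path)
  s <- readStructure(path)
  expect_equal(length(residueKeys(s)), 3L)
  expect_equal(nrow(atoms(s)), 4L)
  expect_false(any(grepl("^H", atoms(s)$elety)))
})

test_that("hydrogens are recognized from atom names when the element column is blank", {
  path <- withr::local_tempfile(fileext = ".pdb")
  df <- rbind(pdbRow(1, "CA", "A", 1, 0, 0, 0, elem = ""),
              pdbRow(2, "1HB", "A", 1, 1, 0, 0, elem = ""),
              pdbRow(3, "HG1", "A", 1, 2, 0, 0, elem = ""))
  writeMiniPdb(df, path)
  s <- readStructure(path)
  expect_equal(nrow(atoms(s)), 1L)
  expect_equal(atoms(s)$elety, "CA")
})

test_that("chain filtering and empty selections behave as specified", {
  path <- withr::local_tempfile(fileext = ".pdb")
  df <- rbind(pdbRow(1, "CA", "A", 1, 0, 0, 0),
              pdbRow(2, "CA", "B", 1, 5, 0, 0))
  writeMiniPdb(df, path)
  sA <- readStructure(path, chains = "A")
  expect_equal(unique(atoms(sA)$chain), "A")
  expect_error(readStructure(path, chains = "Z"), "no residues selected")
  expect_error(readStructure(file.path(tempdir(), "absent.pdb")),
               "absent.pdb")
})

test_that("coordinates round-trip through PDB writing to 3 decimals", {
  fix <- makeMotionFixture("shear", nPerSide = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(fix$conf1, path)
  back <- readStructure(path)
  a0 <- atoms(fix$conf1); a1 <- atoms(back)
  expect_equal(nrow(a0), nrow(a1))
  expect_equal(round(a1$x, 3), round(a0$x, 3))
  expect_equal(round(a1$y, 3), round(a0$y, 3))
  expect_equal(round(a1$z, 3), round(a0$z, 3))
  # parsing is deterministic
  again <- readStructure(path)
  expect_identical(atoms(back), atoms(again))
})

test_that("altlocs keep the first listed location and HETATM is opt-in", {
  path <- withr::local_tempfile(fileext = ".pdb")
  df <- rbind(pdbRow(1, "CA", "A", 1, 0, 0, 0, alt = "A"),
              pdbRow(2, "CA", "A", 1, 9, 9, 9, alt = "B"),
              pdbRow(3, "CA", "A", 2, 5, 0, 0),
              pdbRow(4, "C1", "A", 90, 7, 7, 7, elem = "C", type = "HETATM",
                     resn = "LIG"))
  writeMiniPdb(df, path)
  s <- readStructure(path)
  ca1 <- atoms(s)[atoms(s)$key == "A:1", ]
  expect_equal(nrow(ca1), 1L)
  expect_equal(ca1$x, 0)
  expect_false("A:90" %in% residueKeys(s))
  sh <- readStructure(path, includeHet = TRUE)
  expect_true("A:90" %in% residueKeys(sh))
})

test_that("only the first model of a multi-model file is read", {
  path <- withr::local_tempfile(fileext = ".pdb")
  df <- rbind(pdbRow(1, "CA", "A", 1, 0, 0, 0),
              pdbRow(1, "CA", "A", 1, 50, 50, 50))
  writeMiniPdb(df, path, modelBlocks = list(1L, 2L))
  s <- readStructure(path)
  expect_equal(nrow(atoms(s)), 1L)
  expect_equal(atoms(s)$x, 0)
})

test_that("domain specs expand ranges and enforce disjoint roles", {
  spec <- readDomainSpec(text = c("domainA A:1-50",
                                  "domainB A:55-100",
                                  "bending A:51-54"))
  expect_equal(length(domainA(spec)), 50L)
  expect_equal(length(domainB(spec)), 46L)
  expect_equal(length(bendingResidues(spec)), 4L)
  expect_error(readDomainSpec(text = c("domainA A:1-50", "domainB A:40-90")),
               "both domains")
  one <- readDomainSpec(text = c("domainA A:7-7", "domainB B:1-3"))
  expect_equal(domainA(one), "A:7")
  expect_error(readDomainSpec(text = "domainA A:1-50"), "non-empty")
  expect_error(readDomainSpec(text = c("core A:1-10", "domainB B:1-5")),
               "unknown role")
  # serialization round trip
  path <- withr::local_tempfile()
  writeDomainSpec(spec, path)
  expect_equal(readDomainSpec(path), spec)
})

test_that("axis specs normalize direction and validate fields", {
  path <- withr::local_tempfile()
  writeLines(c("point 0 0 0", "direction 0 0 2", "angle_deg 10",
               "translation_A 1", "percent_closure 84"), path)
  ax <- readScrewAxis(path)
  expect_equal(ax@direction, c(0, 0, 1))
  expect_equal(ax@angle, 10)
  expect_equal(ax@translation, 1)
  expect_equal(ax@percentClosure, 84)
  expect_error(ScrewAxis(c(0, 0, 0), c(0, 0, 0), 10), "zero length")
  expect_error(ScrewAxis(c(0, 0, 0), c(0, 0, 1), 10, percentClosure = 120),
               "percentClosure")
  expect_error(ScrewAxis(c(0, 0, 0), c(0, 0, 1), -3), "angle")
})

test_that("a two-atom arrow PDB defines the axis line", {
  path <- withr::local_tempfile(fileext = ".pdb")
  df <- rbind(pdbRow(1, "X1", "Z", 1, 0, 0, -10, elem = "C", type = "HETATM"),
              pdbRow(2, "X2", "Z", 2, 0, 0, 10, elem = "C", type = "HETATM"))
  writeMiniPdb(df, path)
  ax <- readScrewAxis(path, angle = 15)
  expect_equal(ax@direction, c(0, 0, 1))
  # the stored point lies on the segment
  expect_equal(ax@point, c(0, 0, -10))
  expect_error(readScrewAxis(path), "rotation angle")
})
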