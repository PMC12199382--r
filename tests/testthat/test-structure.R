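test_that("readPDB parses single atoms, fixtures and multi-model files", {
  # identity case: one-ATOM file
  f <- writeFixturePDB(atomLine(1, "CA", "ALA", "A", 1, 1.0, 2.0, 3.0))
  s <- readPDB(f)
  expect_equal(nrow(atomTable(s)), 1L)
  expect_equal(nModels(s), 1L)
  expect_equal(unname(atomCoords(s)[1, ]), c(1, 2, 3))

  # tripeptide fixture: three residues, input order preserved
  lines <- c(atomLine(1, "N", "GLY", "A", 1, 0, 0, 0),
             atomLine(2, "CA", "GLY", "A", 1, 1.4, 0, 0),
             atomLine(3, "N", "ALA", "A", 2, 3.8, 0, 0),
             atomLine(4, "CA", "ALA", "A", 2, 5.2, 0, 0),
             atomLine(5, "N", "SER", "A", 3, 7.6, 0, 0),
             atomLine(6, "CA", "SER", "A", 3, 9.0, 0, 0))
  s <- readPDB(writeFixturePDB(lines))
  expect_equal(residueNumbers(s), 1:3)
  expect_equal(unique(atomTable(s)$resid), c("GLY", "ALA", "SER"))

  # MODEL 1 / MODEL 2: two models with identical atom identities
  mm <- c("MODEL        1", lines[1:2], "ENDMDL",
          "MODEL        2",
          atomLine(1, "N", "GLY", "A", 1, 0.5, 0, 0),
          atomLine(2, "CA", "GLY", "A", 1, 1.9, 0, 0), "ENDMDL", "END")
  s2 <- readPDB(writeFixturePDB(mm))
  expect_equal(nModels(s2), 2L)
  expect_equal(nrow(atomTable(s2)), 2L)
  expect_equal(unname(atomCoords(s2, 2)[1, "x"]), 0.5)
})

test_that("readPDB reports malformed and empty files with context", {
  bad <- c(atomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
           "ATOM      2  CB  ALA A   1      bad_xyz  0.000   0.000")
  expect_error(readPDB(writeFixturePDB(bad)), "line 2")
  expect_error(readPDB(writeFixturePDB("REMARK nothing here")),
               "no ATOM")
  expect_error(readPDB(tempfile()), "not found")
})

test_that("parse -> write -> parse is the identity on identities and coords", {
  for (fixture in list(buildPeptide("GMG"),
                       makePoseEnsemble(c("Fc-VHH" = 2), seed = 1)$
                         ensemble@structure)) {
    f <- tempfile(fileext = ".pdb")
    writePDB(fixture, f)
    back <- readPDB(f)
    expect_equal(atomTable(back)$name, atomTable(fixture)$name)
    expect_equal(atomTable(back)$resno, atomTable(fixture)$resno)
    expect_equal(atomTable(back)$resid, atomTable(fixture)$resid)
    expect_equal(atomTable(back)$chain, atomTable(fixture)$chain)
    expect_equal(nModels(back), nModels(fixture))
    for (k in seq_len(nModels(fixture)))
      expect_equal(atomCoords(back, k), atomCoords(fixture, k),
                   tolerance = 1e-3)
  }
})

test_that("default domain boundaries place the known hotspot residues", {
  # sparse CA-only chain covering the full heavy-chain numbering
  resno <- c(57, 105, 106, 111, 120, 130, 136, 139, 162, 338, 350)
  atoms <- data.frame(name = "CA", resno = resno, resid = "ALA",
                      chain = "A")
  s <- proteinStructure(atoms, cbind(resno * 4, 0, 0))
  ann <- annotateDomains(s)
  expect_equal(unname(domainOf(ann, c(130, 136, 139))),
               rep("hinge", 3))
  expect_equal(unname(domainOf(ann, c(57, 105, 106, 111, 120))),
               rep("VHH", 5))
  expect_equal(unname(domainOf(ann, c(162, 338))), rep("Fc", 2))
})

test_that("domain annotation is a partition and rejects gaps/overlaps", {
  s <- buildPeptide(strrep("A", 12))
  ann <- annotateDomains(s, boundaries = list(VHH = c(1, 6),
                                              hinge = c(7, 9),
                                              Fc = c(10, 12)))
  lab <- domainOf(ann, 1:12)
  expect_false(anyNA(lab))            # every residue labelled
  expect_equal(sum(lab == "VHH") + sum(lab == "hinge") + sum(lab == "Fc"),
               12L)                   # exactly one domain each
  expect_error(annotateDomains(s, boundaries = list(VHH = c(1, 6),
                                                    Fc = c(9, 12))),
               "unassigned.*7, 8")
  expect_error(annotateDomains(s, boundaries = list(VHH = c(1, 7),
                                                    hinge = c(7, 9),
                                                    Fc = c(10, 12))),
               "overlap")
})

test_that("kabatCDRs honours overrides and anchors the canonical ranges", {
  ov <- kabatCDRs("X", override = list(c(26, 35), c(50, 65), c(95, 112)))
  expect_equal(IRanges::start(ov), c(26, 50, 95))
  expect_equal(IRanges::end(ov), c(35, 65, 112))

  # synthetic anchored sequence: C22, W36, C92, W103-G104-x-G106.
  # Hand application of the anchor rules gives 31-35 / 50-65 / 95-102.
  s <- rep("A", 110)
  s[c(22, 92)] <- "C"
  s[c(36, 103)] <- "W"
  s[c(104, 106)] <- "G"
  rng <- kabatCDRs(paste(s, collapse = ""))
  expect_equal(unname(IRanges::start(rng)), c(31, 50, 95))
  expect_equal(unname(IRanges::end(rng)), c(35, 65, 102))

  # no Trp after the putative CDR3 -> instructive error
  s2 <- s
  s2[103] <- "A"
  expect_error(kabatCDRs(paste(s2, collapse = "")), "override")
})
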