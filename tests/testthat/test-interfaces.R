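test_that("pose ensembles load from multi-model PDB with energy joining", {
  fx <- makePoseEnsemble(c("Fc-VHH" = 3, "VHH-VHH" = 1), seed = 3)
  f <- tempfile(fileext = ".pdb")
  writePDB(fx$ensemble@structure, f)

  one <- makePoseEnsemble(c("Fc-Fc" = 1), seed = 1)
  f1 <- tempfile(fileext = ".pdb")
  writePDB(one$ensemble@structure, f1)
  expect_equal(nPoses(loadPoseEnsemble(f1)), 1L)

  etab <- data.frame(pose_index = 1:4,
                     energy_kcal_mol = c(-57, -60, -55, -40))
  ens <- loadPoseEnsemble(f, energies = etab)
  expect_equal(nPoses(ens), 4L)
  expect_equal(poseEnergies(ens), etab$energy_kcal_mol)

  expect_error(loadPoseEnsemble(f, energies = etab[1:3, ]), "3 rows")
  # one partner group only -> error
  solo <- buildPeptide("AAA")
  fs <- tempfile(fileext = ".pdb")
  writePDB(solo, fs)
  expect_error(loadPoseEnsemble(fs), "two partner groups")
})

test_that("interface contacts match the exhaustive pairwise oracle", {
  fx <- makePoseEnsemble(c("hinge-VHH" = 2), seed = 5)
  for (k in 1:2) {
    got <- interfaceContacts(fx$ensemble, k)
    want <- oracleContacts(fx$ensemble, k)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$rec_atom, want$rec_atom)
    expect_equal(got$lig_atom, want$lig_atom)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
  }
  # symmetry under swapping receptor/ligand labels
  sw <- fx$ensemble
  sw@receptorChains <- "B"
  sw@ligandChains <- "A"
  a <- interfaceContacts(fx$ensemble, 1)
  b <- interfaceContacts(sw, 1)
  expect_equal(nrow(a), nrow(b))
  expect_setequal(paste(a$rec_atom, a$lig_atom),
                  paste(b$lig_atom, b$rec_atom))
})

test_that("contact boundary at exactly the cutoff is inclusive", {
  mk <- function(d) {
    atoms <- data.frame(name = "CA", resno = c(1L, 1L),
                        resid = "ALA", chain = c("A", "B"))
    proteinStructure(atoms, rbind(c(0, 0, 0), c(d, 0, 0)))
  }
  at <- poseEnsemble(mk(5.0))
  expect_equal(nrow(interfaceContacts(at)), 1L)
  beyond <- poseEnsemble(mk(5.001))
  expect_equal(nrow(interfaceContacts(beyond)), 0L)
  far <- poseEnsemble(mk(100))
  expect_equal(nrow(interfaceContacts(far)), 0L)
  expect_equal(classifyBindingMode(far, makePoseEnsemble(
    c("Fc-Fc" = 1), seed = 1)$annotation), "unbound")
})

test_that("binding modes recover the planted distribution", {
  fx <- makePoseEnsemble(c("Fc-Fc" = 2, "Fc-VHH" = 3, "VHH-VHH" = 1,
                           "hinge-hinge" = 1, "Fc-hinge" = 2,
                           "hinge-VHH" = 1), seed = 11)
  got <- vapply(seq_len(nPoses(fx$ensemble)), function(k)
    classifyBindingMode(fx$ensemble, fx$annotation, k), character(1))
  expect_equal(got, fx$truth$modes)
})

test_that("mode summary reports counts, percentages and energies per mode", {
  fx <- makePoseEnsemble(c("Fc-VHH" = 3, "VHH-VHH" = 1), seed = 2,
                         energyPerMode = c("Fc-VHH" = -57, "VHH-VHH" = -45))
  ms <- modeSummary(fx$ensemble, fx$annotation)
  expect_equal(ms$count[ms$mode == "Fc-VHH"], 3L)
  expect_equal(ms$percentage[ms$mode == "Fc-VHH"], 75)
  expect_equal(ms$percentage[ms$mode == "VHH-VHH"], 25)
  expect_equal(sum(ms$percentage), 100, tolerance = 1e-9)
  expect_false(is.na(ms$mean_energy[ms$mode == "Fc-VHH"]))
  expect_true(is.na(ms$mean_energy[ms$mode == "Fc-Fc"]))
  expect_equal(ms$mode, c("Fc-Fc", "Fc-VHH", "Fc-hinge", "hinge-hinge",
                          "hinge-VHH", "VHH-VHH"))
  # single-mode ensemble -> 100%
  one <- makePoseEnsemble(c("hinge-hinge" = 2), seed = 4)
  m1 <- modeSummary(one$ensemble, one$annotation)
  expect_equal(m1$percentage[m1$mode == "hinge-hinge"], 100)
})

test_that("PPIP counts match brute force, normalise to 1 and combine ensembles", {
  fx <- makePoseEnsemble(c("Fc-VHH" = 2), seed = 9)
  pm <- ppiPreference(fx$ensemble)
  counts <- contactCounts(pm)
  truth <- fx$truth$counts
  expect_equal(counts[names(truth)], truth[names(truth)],
               ignore_attr = TRUE)
  expect_equal(max(preference(pm)), 1.0)
  expect_true(all(preference(pm) >= 0 & preference(pm) <= 1))
  # positions never at an interface are 0
  expect_true(any(preference(pm) == 0))

  # combining ensembles = one global normalisation of the summed counts
  fy <- makePoseEnsemble(c("VHH-VHH" = 1), seed = 10)
  both <- ppiPreference(list(fx$ensemble, fy$ensemble))
  merged <- fx$truth$counts
  for (rr in names(fy$truth$counts))
    merged[rr] <- (if (rr %in% names(merged)) merged[[rr]] else 0L) +
      fy$truth$counts[[rr]]
  expect_equal(contactCounts(both)[names(merged)], merged,
               ignore_attr = TRUE)
  expect_equal(max(preference(both)), 1.0)
})

test_that("the aggregation interface applies a strict preference threshold", {
  pm <- new("PPIPMap", counts = c(`1` = 10L, `2` = 4L, `3` = 6L),
            preference = c(`1` = 1.0, `2` = 0.4, `3` = 0.6))
  expect_equal(aggregationInterface(pm), c(1L, 3L))
  expect_equal(aggregationInterface(pm, threshold = 1.0), integer(0))
  low <- new("PPIPMap", counts = c(`1` = 2L, `2` = 1L),
             preference = c(`1` = 1.0, `2` = 0.5))
  expect_equal(aggregationInterface(low), 1L)  # 0.5 is not > 0.5
})
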