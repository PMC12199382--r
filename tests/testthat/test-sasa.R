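test_that("isolated atom SASA matches the analytic sphere area", {
  s <- proteinStructure(data.frame(name = "C", resno = 1L, resid = "DUM",
                                   chain = "A"),
                        matrix(0, 1, 3))
  got <- atomSASA(shrakeRupley(s))[1, 1]
  expect_equal(got, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
})

test_that("an atom enclosed by a dense cage has zero SASA", {
  shell <- HcAbStab:::.spherePoints(400) * 3.2
  atoms <- data.frame(name = "C",
                      resno = seq_len(nrow(shell) + 1L),
                      resid = "DUM", chain = "A")
  s <- proteinStructure(atoms, rbind(c(0, 0, 0), shell))
  expect_equal(atomSASA(shrakeRupley(s))[1, 1], 0)
})

test_that("per-atom SASA agrees with an independent high-density oracle", {
  for (seq in c("GM", "FD")) {
    pep <- buildPeptide(seq)
    got <- atomSASA(shrakeRupley(pep, nPoints = 3000))[, 1]
    want <- oracleSASA(pep, nTheta = 200, nPhi = 400)  # 80000-point oracle
    # 5 A^2 floor: atoms with almost no exposed area are compared
    # absolutely (to 0.1 A^2) rather than relatively
    rel <- abs(got - want) / pmax(want, 5)
    expect_lt(max(rel), 0.02)
  }
})

test_that("SASA is translation invariant and rotation invariant to quadrature noise", {
  pep <- buildPeptide("AFK")
  base <- atomSASA(shrakeRupley(pep))[, 1]
  set.seed(11)
  for (rep in 1:3) {
    t <- stats::rnorm(3, sd = 20)
    moved <- proteinStructure(atomTable(pep),
                              atomCoords(pep) +
                                matrix(t, nrow(atomTable(pep)), 3, byrow = TRUE))
    got <- atomSASA(shrakeRupley(moved))[, 1]
    expect_equal(got, base, tolerance = 1e-12)
    # random rotation: invariant up to the fixed-point-set quadrature noise
    ang <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    rot <- proteinStructure(atomTable(pep), atomCoords(pep) %*% t(R))
    gotR <- atomSASA(shrakeRupley(rot))[, 1]
    sphere <- 4 * pi * (atomTable(pep)$radius + 1.4)^2
    expect_lt(max(abs(gotR - base) / sphere), 0.0075)
  }
})

test_that("adding an atom never increases any other atom's SASA", {
  pep <- buildPeptide("GMG")
  base <- atomSASA(shrakeRupley(pep))[, 1]
  a <- atomTable(pep)
  extra <- data.frame(serial = NA_integer_, name = "C", element = "C",
                      resno = max(a$resno) + 1L, resid = "DUM", chain = "Z",
                      radius = 1.7, type = "HETATM")
  grown <- proteinStructure(rbind(a[names(a)], extra[names(a)]),
                            rbind(atomCoords(pep),
                                  colMeans(atomCoords(pep)) + c(4, 0, 0)))
  withExtra <- atomSASA(shrakeRupley(grown))[seq_along(base), 1]
  expect_true(all(withExtra <= base + 1e-9))
})

test_that("doubling the quadrature density changes SASA by < 0.5%", {
  pep <- buildPeptide("CT")
  lo <- atomSASA(shrakeRupley(pep, nPoints = 2000))[, 1]
  hi <- atomSASA(shrakeRupley(pep, nPoints = 4000))[, 1]
  sphere <- 4 * pi * (atomTable(pep)$radius + 1.4)^2
  expect_lt(max(abs(hi - lo) / sphere), 0.005)
})

test_that("relative SASA reproduces the reference arithmetic", {
  pep <- buildPeptide("GMG")
  prof <- shrakeRupley(pep)
  res <- residueSASA(prof)
  met <- res$sasa[res$resno == 2]
  rel <- relativeSASA(prof, residues = 2)
  expect_equal(rel$pct, 100 * met / maxASARef()[["MET"]])
  # absolute 47.5 with the Met reference 231.7 implies 20.5%
  expect_equal(round(100 * 47.5 / maxASARef()[["MET"]], 1), 20.5)
  # zero SASA -> 0%; reference-equal SASA -> 100% (scale checks on the map)
  expect_error(relativeSASA(prof, reference = c(GLY = 104)), "MET")
})

test_that("hydrophobic patches match the brute-force clustering oracle", {
  # two Leu/Phe clusters separated by a long polar spacer
  pep <- buildPeptide("LFLSSSSSSSSLFL")
  prof <- shrakeRupley(pep)
  patches <- hydrophobicPatches(pep, prof, minArea = 20, cutoff = 4.5)
  # oracle: cluster the same candidate atoms naively
  a <- atomTable(pep)
  s <- rowMeans(atomSASA(prof))
  tab <- hydrophobicAtomTable()
  phi <- mapply(function(resid, name) {
    v <- tab[[resid]]
    if (!is.null(v) && name %in% names(v)) v[[name]] else 0
  }, a$resid, a$name)
  idx <- which(s > 0.1 & phi > 0)
  comp <- oracleClusters(atomCoords(pep)[idx, , drop = FALSE], 4.5)
  areas <- sort(tapply(s[idx], comp, sum), decreasing = TRUE)
  areas <- areas[areas > 20]
  expect_equal(nrow(patches), length(areas))
  expect_equal(patches$area, as.numeric(areas))
  # the polar spacer separates the two hydrophobic ends: no patch spans both
  for (r in patches$residues)
    expect_true(all(r <= 3) || all(r >= 12))

  # all-polar surface: no patches
  ser <- buildPeptide("SSSSSS")
  expect_equal(nrow(hydrophobicPatches(ser, shrakeRupley(ser))), 0L)
})

test_that("ionic patches follow charge placement and the area threshold", {
  neutral <- buildPeptide("SGSGSG")
  expect_equal(nrow(ionicPatches(neutral, shrakeRupley(neutral))), 0L)

  kk <- buildPeptide("KKK")
  pk <- ionicPatches(kk, shrakeRupley(kk), minArea = 20)
  expect_true(all(pk$kind == "positive"))
  expect_gte(nrow(pk), 1L)

  # below-threshold summed area yields no patch
  dd <- buildPeptide("DD")
  profDD <- shrakeRupley(dd)
  areaDD <- sum(rowMeans(atomSASA(profDD))[
    atomTable(dd)$name %in% c("OD1", "OD2")])
  got <- ionicPatches(dd, profDD, minArea = areaDD + 5)
  expect_equal(nrow(got), 0L)

  # patch areas of one kind never exceed the total SASA
  pep <- buildPeptide("KDKDEK")
  prof <- shrakeRupley(pep)
  patches <- ionicPatches(pep, prof, minArea = 0.5)
  total <- sum(rowMeans(atomSASA(prof)))
  for (kind in unique(patches$kind))
    expect_lte(sum(patches$area[patches$kind == kind]), total)
})
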