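test_that("oxidation thresholds are strict inequalities at the boundary", {
  ref <- maxASARef()
  mk <- function(resid, pct) {
    # synthetic profile: one residue with exactly the requested SASA%
    atoms <- data.frame(serial = 1L, name = "CA", element = "C",
                        resno = 1L, resid = resid, chain = "A",
                        type = "ATOM")
    new("SASAProfile", atoms = atoms,
        sasa = matrix(pct / 100 * ref[[resid]]), probe = 1.4,
        nPoints = 960L)
  }
  for (pct in c(19.9, 20.0, 20.1)) {
    flag <- oxidationRisk(mk("MET", pct))$flagged
    expect_identical(flag, pct > 20)
  }
  for (pct in c(29.9, 30.0, 30.1)) {
    flag <- oxidationRisk(mk("TRP", pct))$flagged
    expect_identical(flag, pct > 30)
  }
})

test_that("exposed and buried Met/Trp fixtures flag as planted", {
  fx <- makeToyStructure(list(sequence = "GAMAG"))       # exposed Met
  prof <- shrakeRupley(fx$structure)
  ox <- oxidationRisk(prof)
  expect_true(ox$flagged[ox$resid == "MET"])

  bw <- makeToyStructure(list(sequence = "GAWAG", buried = 3))
  oxw <- oxidationRisk(shrakeRupley(bw$structure))
  expect_false(oxw$flagged[oxw$resid == "TRP"])
})

test_that("histidine catalysis needs a close His plus an exposure route", {
  # exposed Met with His at 8 A: self-flagged, His within 10 -> TRUE
  fx <- makeToyStructure(list(sequence = "GAMAG",
                              hisNear = list(target = 3, distance = 8)))
  flags <- oxidationRisk(shrakeRupley(fx$structure))
  hc <- hisCatalysis(fx$structure, 3, flags)
  expect_true(hc$his_catalysis)
  expect_equal(nrow(hc$nearby_his), 1L)
  expect_equal(hc$nearby_his$distance, 8, tolerance = 0.1)

  # His beyond 10 A -> FALSE (matches the brute-force distance check)
  far <- makeToyStructure(list(sequence = "GAMAG",
                               hisNear = list(target = 3, distance = 11)))
  flagsFar <- oxidationRisk(shrakeRupley(far$structure))
  expect_false(hisCatalysis(far$structure, 3, flagsFar)$his_catalysis)

  # no His anywhere -> FALSE
  noh <- makeToyStructure(list(sequence = "GAMAG"))
  flagsNoh <- oxidationRisk(shrakeRupley(noh$structure))
  expect_false(hisCatalysis(noh$structure, 3, flagsNoh)$his_catalysis)

  # buried Met rescued by a flagged Met sulfur within the pair radius:
  # two Met five residues apart in a helix end up with close sulfurs
  expect_error(hisCatalysis(noh$structure, 2, flagsNoh), "not a methionine")
})

test_that("a buried Met with His nearby and a flagged Met pair is catalysis-prone", {
  # helix brings i, i+4 side chains together
  pep <- buildPeptide("AMAAMA", conformation = "helix")
  a <- atomTable(pep)
  sds <- which(a$name == "SD")
  dSS <- sqrt(sum((atomCoords(pep)[sds[1], ] - atomCoords(pep)[sds[2], ])^2))
  prof <- shrakeRupley(pep)
  flags <- oxidationRisk(prof)
  # force the synthetic exposure pattern: Met2 flagged, Met5 not
  flags$flagged[flags$resno == 2] <- TRUE
  flags$flagged[flags$resno == 5] <- FALSE
  fakeHis <- data.frame(serial = NA_integer_, name = "NE2", element = "N",
                        resno = 50L, resid = "HIS", chain = "B",
                        radius = 1.55, type = "ATOM")
  target <- atomCoords(pep)[sds[2], ] + c(0, 4, 0)
  grown <- proteinStructure(rbind(a[names(a)], fakeHis[names(a)]),
                            rbind(atomCoords(pep), target))
  hc <- hisCatalysis(grown, 5, flags, chain = "A",
                     metPairRadius = dSS + 0.5)
  expect_true(hc$his_catalysis)
  expect_equal(nrow(hc$paired_met), 1L)
  # same geometry but the paired Met not flagged -> FALSE
  flags$flagged[flags$resno == 2] <- FALSE
  expect_false(hisCatalysis(grown, 5, flags, chain = "A",
                            metPairRadius = dSS + 0.5)$his_catalysis)
})

test_that("the STAP filter applies score, interface and conservation rules", {
  scores <- c(`5` = 1.2, `11` = 1.6, `57` = 1.4, `58` = 1.1, `59` = 1.3,
              `103` = 1.2, `105` = 1.8, `106` = 1.7, `120` = 1.1,
              `90` = 0.4)
  interface <- c(57, 58, 59, 105, 106, 120, 90)
  conserved <- c(58, 59)
  got <- stapFilter(scores, interface, conserved)
  expect_equal(got, c(57L, 105L, 106L, 120L))
  expect_equal(stapFilter(scores, integer(0), conserved), integer(0))
  expect_equal(stapFilter(scores, interface, as.integer(names(scores))),
               integer(0))
  # monotone in the conserved set and threshold
  expect_true(all(stapFilter(scores, interface, c(conserved, 57)) %in% got))
  expect_true(all(stapFilter(scores, interface, conserved,
                             threshold = 1.5) %in% got))
  # data.frame input equivalent
  df <- data.frame(resno = as.integer(names(scores)), score = scores)
  expect_equal(stapFilter(df, interface, conserved), got)
})

test_that("binding-critical residues use the strict 1 kcal/mol rule", {
  ddg <- c(`55` = 2.1, `59` = 1.6, `62` = 1.2, `105` = 3.0, `106` = 2.8,
           `107` = 1.1, `50` = 0.4, `58` = 1.0)
  got <- bindingCritical(ddg)
  expect_equal(got, c(55L, 59L, 62L, 105L, 106L, 107L))
  expect_false(58 %in% got)  # exactly 1.0 excluded
  expect_equal(bindingCritical(c(`1` = 0.2, `2` = 1.0)), integer(0))
})

test_that("the hotspot report merges reasons and enforces exclusions", {
  redox <- data.frame(bond_label = c("C130-C130", "C136-C136"),
                      resno = c(130L, 136L),
                      classification = c("reduction-prone", "stabilizing"))
  oxidation <- data.frame(chain = "A", resno = c(111L, 115L),
                          resid = "TRP", sasa_pct = c(69.2, 28.0),
                          threshold = 30, flagged = c(TRUE, FALSE))
  stap <- c(57L, 105L, 106L, 120L)
  bc <- c(55L, 59L, 62L, 105L, 106L, 107L)
  rep <- hotspotReport(redox = redox, oxidation = oxidation, stap = stap,
                       bindingCritical = bc, conserved = c(58L, 59L, 115L))
  tab <- reportTable(rep)
  expect_setequal(tab$resno, c(130, 57, 105, 106, 120, 111))
  expect_false(136 %in% tab$resno)  # stabilizing bond contributes nothing
  expect_false(115 %in% tab$resno)  # unflagged Trp contributes nothing
  y <- tab[tab$resno %in% c(105, 106), ]
  expect_true(all(!y$mutable))
  expect_true(all(grepl("binding-critical", y$excluded_because)))
  expect_setequal(mutableHotspots(rep), c(130, 57, 120, 111))
  # a residue both STAP and binding-critical is listed but never mutable
  expect_true(all(c(105, 106) %in% tab$resno))
  # empty inputs -> empty report
  empty <- hotspotReport()
  expect_equal(nrow(reportTable(empty)), 0L)
})

test_that("set rules agree with a brute-force reimplementation on random inputs", {
  set.seed(42)
  for (i in 1:25) {
    resno <- sample(1:60, 30)
    scores <- stats::runif(30, 0, 2)
    names(scores) <- resno
    interface <- sample(1:60, sample(0:25, 1))
    conserved <- sample(1:60, sample(0:10, 1))
    thr <- stats::runif(1, 0.5, 1.5)
    got <- stapFilter(scores, interface, conserved, thr)
    want <- integer(0)
    for (r in resno)
      if (scores[[as.character(r)]] > thr && r %in% interface &&
          !(r %in% conserved)) want <- c(want, r)
    expect_equal(got, sort(as.integer(want)))
  }
})
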