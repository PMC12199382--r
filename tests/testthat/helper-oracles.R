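# Independent oracles used by the tests. These deliberately share no code
# with the package implementations: different quadrature, plain double
# loops, naive set arithmetic.

# SASA oracle: latitude-longitude quadrature with sin(theta) weights,
# naive all-pairs neighbour blocking.
oracleSASA <- function(structure, probe = 1.4, nTheta = 100, nPhi = 200,
                       model = 1L) {
  a <- atomTable(structure)
  xyz <- atomCoords(structure, model)
  radii <- a$radius + probe
  n <- nrow(a)
  theta <- (seq_len(nTheta) - 0.5) * pi / nTheta
  phi <- (seq_len(nPhi) - 0.5) * 2 * pi / nPhi
  grid <- expand.grid(theta = theta, phi = phi)
  dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi),
                cos(grid$theta))
  w <- sin(grid$theta)
  w <- w / sum(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- dirs * radii[i] + matrix(xyz[i, ], nrow(dirs), 3, byrow = TRUE)
    acc <- rep(TRUE, nrow(pts))
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= radii[j]^2
    }
    out[i] <- 4 * pi * radii[i]^2 * sum(w[acc])
  }
  out
}

# SAP oracle: enumerate every (atom, residue) pair with plain loops and
# recompute the partial side-chain accessibilities from the profile.
oracleSAP <- function(structure, profile, radius = 5.0,
                      scale = sapHydrophobicityScale(),
                      reference = sidechainRefSASA()) {
  a <- atomTable(structure)
  xyz <- atomCoords(structure)
  sasa <- atomSASA(profile)[, 1]
  bb <- c("N", "CA", "C", "O", "OXT")
  n <- nrow(a)
  out <- numeric(n)
  reskeys <- unique(paste(a$chain, a$resno))
  for (i in seq_len(n)) {
    total <- 0
    for (rk in reskeys) {
      rows <- which(paste(a$chain, a$resno) == rk)
      dmin <- Inf
      num <- 0
      for (j in rows) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        dmin <- min(dmin, d)
        if (d <= radius && !(a$name[j] %in% bb)) num <- num + sasa[j]
      }
      if (dmin <= radius) {
        rt <- a$resid[rows[1]]
        ref <- if (rt %in% names(reference)) reference[[rt]] else 0
        phi <- if (rt %in% names(scale)) scale[[rt]] else 0
        if (ref > 0 && phi != 0) total <- total + num / ref * phi
      }
    }
    out[i] <- total
  }
  out
}

# contact oracle: plain double loop over cross-partner heavy atoms
oracleContacts <- function(ensemble, pose = 1L, cutoff = 5.0) {
  a <- atomTable(ensemble@structure)
  xyz <- atomCoords(ensemble@structure, pose)
  rec <- which(a$chain %in% ensemble@receptorChains & a$element != "H")
  lig <- which(a$chain %in% ensemble@ligandChains & a$element != "H")
  hits <- list()
  for (i in rec) for (j in lig) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff)
      hits[[length(hits) + 1L]] <- data.frame(rec_atom = i, lig_atom = j,
                                              distance = d)
  }
  if (!length(hits))
    return(data.frame(rec_atom = integer(0), lig_atom = integer(0),
                      distance = numeric(0)))
  do.call(rbind, hits)
}

# connected-components oracle: naive repeated merging at the cutoff
oracleClusters <- function(xyz, cutoff) {
  n <- nrow(xyz)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# tiny PDB fixture writers
writeFixturePDB <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

atomLine <- function(serial, name, resid, chain, resno, x, y, z,
                     element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resid, chain, resno, x, y, z, element)
}
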