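test_that("peptide builder: determinism, caps, backbone geometry", {
  a <- buildPeptide("SNNFGAILSS")
  b <- buildPeptide("SNNFGAILSS")
  expect_identical(a@coords[[1]], b@coords[[1]])
  rn <- vapply(residues(a), function(r) r$name, "")
  expect_equal(rn[1], "ACE")
  expect_equal(rn[length(rn)], "NH2")
  expect_equal(vapply(residues(a), function(r) r$seqNumber, 1)[2], 20)
  # bond lengths of the internal-coordinate chain
  at <- atoms(a); x <- a@coords[[1]]
  n1 <- which(at$name == "N" & at$resIndex == 2)
  ca1 <- which(at$name == "CA" & at$resIndex == 2)
  c1 <- which(at$name == "C" & at$resIndex == 2)
  expect_equal(sqrt(sum((x[ca1, ] - x[n1, ])^2)), 0.1458, tolerance = 1e-9)
  expect_equal(sqrt(sum((x[c1, ] - x[ca1, ])^2)), 0.1525, tolerance = 1e-9)
  expect_error(buildPeptide("AZ"), "unknown residue")
  expect_error(buildPeptide("A"), "at least 2")
})

test_that("ligand template: planarity, donors, heavy-atom count", {
  lig <- buildLigand()
  expect_equal(nrow(chains(lig)), 1L)
  expect_equal(chains(lig)$kind, "ligand")
  expect_equal(sum(!atoms(lig)$isHydrogen), 17L)
  r <- residues(lig)[[1]]
  expect_equal(nrow(r$donors), 2L)       # indole N-H and amide N-H
  expect_length(r$acceptors, 2L)         # amide carbonyl O and methoxy O
  expect_length(r$rings, 2L)
  expect_equal(sort(lengths(r$rings)), c(5L, 6L))
  benzene <- oligolens:::ligandBenzeneRing(topology(lig))
  rg <- ringGeometry(lig@coords[[1]][benzene, ])
  expect_lt(rg$planarityRmsd, 0.001)
})

test_that("sheet oligomer: parallel E, spacing contract, distant strands unbonded", {
  sh <- buildSheetOligomer(2)
  ss <- ssCodes(assignSecondaryStructure(sh))[1, ]
  expect_true(all(ss[c(3:8, 13:18)] == "E"))
  expect_error(buildSheetOligomer(2, strandSpacing = 0), "positive")
  expect_error(buildSheetOligomer(1), "at least 2")
  farApart <- buildSheetOligomer(2, strandSpacing = 3)
  hb <- detectHBonds(farApart)
  chainOf <- vapply(residues(topology(farApart)), function(r) r$chainId, "")
  expect_equal(sum(chainOf[hb$donorRes] != chainOf[hb$acceptorRes]), 0L)
})

test_that("stacked placement is inverted by the stacking detector", {
  strand <- buildPeptide("SNNFGAILSS")
  phe <- ringSelection(topology(strand), "resname PHE")[[1]]
  rg <- ringGeometry(strand@coords[[1]][phe, ])
  lig <- buildLigand()
  set.seed(41)
  cases <- rbind(c(60, 0.48), c(0, 0.40),
                 cbind(runif(20, 0, 90), runif(20, 0.35, 0.8)))
  for (k in seq_len(nrow(cases))) {
    placed <- placeLigandStacked(lig, rg, cases[k, 1], cases[k, 2])
    sys <- mergeSystems(list(strand, placed))
    st <- stackingEvents(sys, ringSelection(topology(sys), "peptide and resname PHE"),
                         ringSelection(topology(sys), "ligand"))
    expect_equal(st$angle, cases[k, 1], tolerance = 0.1)
    expect_equal(st$distance, cases[k, 2], tolerance = 0.001)
  }
  # classification thresholds
  p1 <- placeLigandStacked(lig, rg, 0, 0.40)
  s1 <- stackingEvents(mergeSystems(list(strand, p1)),
                       ringSelection(topology(strand), "resname PHE"),
                       list(oligolens:::ligandBenzeneRing(topology(p1)) +
                              nAtoms(strand)))
  expect_equal(s1$classification, "parallel")
  p2 <- placeLigandStacked(lig, rg, 60, 0.48)
  s2 <- stackingEvents(mergeSystems(list(strand, p2)),
                       ringSelection(topology(strand), "resname PHE"),
                       list(oligolens:::ligandBenzeneRing(topology(p2)) +
                              nAtoms(strand)))
  expect_equal(s2$classification, "herringbone")
})

test_that("closest-ring pairing picks the nearest candidate", {
  strand <- buildPeptide("SNNFGAILSS")
  phe <- ringSelection(topology(strand), "resname PHE")[[1]]
  rg <- ringGeometry(strand@coords[[1]][phe, ])
  lig <- buildLigand()
  placed <- lapply(c(0.5, 0.7, 0.9), function(d)
    placeLigandStacked(lig, rg, 0, d))
  sys <- mergeSystems(c(list(strand), placed))
  st <- stackingEvents(sys, ringSelection(topology(sys), "peptide and resname PHE"),
                       ringSelection(topology(sys), "ligand"))
  expect_equal(st$distance, 0.5, tolerance = 1e-6)
  expect_equal(st$ringB, 1L)
})

test_that("CH-pi distances: prescribed placement, minimum rule, brute-force oracle", {
  strand <- buildPeptide("SNNFGAILSS")
  top <- topology(strand)
  ileRes <- which(vapply(residues(top), function(r) r$name == "ILE", TRUE))
  cd1 <- residues(top)[[ileRes]]$methyls
  cd1 <- cd1[atoms(top)$name[cd1] == "CD1"]
  x <- strand@coords[[1]]
  lig <- buildLigand()
  benz <- oligolens:::ligandBenzeneRing(topology(lig))
  rgL <- ringGeometry(lig@coords[[1]][benz, ])
  # move the ligand so its benzene centroid sits 0.36 nm from CD1
  target <- x[cd1, ] + c(0, 0, 0.36)
  shifted <- lig
  shifted@coords <- list(sweep(lig@coords[[1]], 2, target - rgL$centroid, "+"))
  sys <- mergeSystems(list(strand, shifted))
  ringsB <- ringSelection(topology(sys), "ligand")
  d <- chpiMinDistance(sys, "resname ILE", ringsB)
  expect_lte(d, 0.36 + 1e-9)   # CD1 at 0.36; CG2 could only be closer
  expect_equal(d, min(vapply(residues(topology(sys))[[ileRes]]$methyls,
    function(m) sqrt(sum((sys@coords[[1]][m, ] -
      ringGeometry(sys@coords[[1]][ringsB[[1]], ])$centroid)^2)), 0)),
    tolerance = 1e-12)
  # residues without methyl annotation are an error
  expect_error(chpiMinDistance(sys, "resname PHE", ringsB), "methyl")
  # brute-force oracle over random placements, both ILE and LEU
  set.seed(43)
  for (rep in 1:5) {
    mv <- lig
    mv@coords <- list(sweep(lig@coords[[1]] %*% t(randomRotationMatrix()),
                            2, runif(3, -1, 1), "+"))
    sys2 <- mergeSystems(list(strand, mv))
    rb <- ringSelection(topology(sys2), "ligand")
    got <- chpiMinDistance(sys2, "resname ILE,LEU", rb)
    topS <- topology(sys2); xs <- sys2@coords[[1]]
    methyls <- unlist(lapply(residues(topS), function(r)
      if (r$name %in% c("ILE", "LEU")) r$methyls else integer(0)))
    best <- Inf
    for (r in rb) {
      cen <- ringGeometry(xs[r, ])$centroid
      for (m in methyls) best <- min(best, sqrt(sum((xs[m, ] - cen)^2)))
    }
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("generated ensembles are deterministic and clash-free", {
  sp <- scenarioSpec(nPeptides = 3, nLigands = 2, nFrames = 4, seed = 27)
  t1 <- generateEnsemble(sp)
  t2 <- generateEnsemble(sp)
  expect_identical(t1@coords, t2@coords)
  t3 <- generateEnsemble(scenarioSpec(nPeptides = 3, nLigands = 2, nFrames = 4,
                                      seed = 28))
  expect_false(identical(t1@coords, t3@coords))
  # no inter-chain heavy-atom distance below 0.2 nm in any frame
  top <- topology(t1)
  heavy <- atomSelect(top, "heavy")
  chainOf <- vapply(residues(top), function(r) r$chainId, "")
  cid <- match(chainOf[atoms(top)$resIndex[heavy]], chains(top)$id)
  for (f in seq_len(nFrames(t1))) {
    x <- t1@coords[[f]][heavy, ]
    d <- oligolens:::cpp_group_min_dist(x, cid, max(cid), x, cid, max(cid),
                                        t1@box[[f]])
    offDiag <- d[row(d) != col(d)]
    expect_gte(min(offDiag), 0.2)
  }
})

test_that("pure-sheet composition drives interior residues to beta", {
  sp <- scenarioSpec(nPeptides = 4, nLigands = 0,
                     composition = c(`beta-sheet` = 1), nFrames = 20,
                     noiseSigma = 0, seed = 51)
  tr <- generateEnsemble(sp)
  ss <- assignSecondaryStructure(tr)
  perRes <- ssPopulation(ss, perResidue = TRUE)
  interior <- perRes[perRes$category == "beta-sheet" &
                       perRes$label %in% c("N22", "F23", "G24", "A25", "I26", "L27"), ]
  expect_true(all(interior$fraction > 0.95))
})

test_that("composition targets are recovered at moderate frame counts", {
  sp <- scenarioSpec(nPeptides = 8, nLigands = 0,
                     composition = c(`beta-sheet` = 0.25, coil = 0.5),
                     nFrames = 150, seed = 61)
  tr <- generateEnsemble(sp)
  pop <- ssPopulation(assignSecondaryStructure(tr))
  expect_lt(abs(pop$fraction[pop$category == "beta-sheet"] - 0.25), 0.04)
  expect_lt(abs(pop$fraction[pop$category == "coil"] - 0.5), 0.04)
})

test_that("random ligand placement keeps every copy at least 2 nm from peptides", {
  sp <- scenarioSpec(nPeptides = 2, nLigands = 6, nFrames = 3, seed = 71)
  tr <- generateEnsemble(sp)
  top <- topology(tr)
  pep <- atomSelect(top, "peptide and heavy")
  lig <- atomSelect(top, "ligand and heavy")
  for (f in 1:3) {
    x <- tr@coords[[f]]
    d <- oligolens:::cpp_group_min_dist(x[pep, ], rep(1L, length(pep)), 1L,
                                        x[lig, ], rep(1L, length(lig)), 1L,
                                        tr@box[[f]])
    expect_gte(d[1, 1], 2 - 0.05)  # noise jitter allowance
  }
})
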