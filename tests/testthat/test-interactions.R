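test_that("residue contact honours the 0.54 nm heavy-atom cutoff; hydrogens never count", {
  near <- pointResidueSystem(list(c(0, 0, 0), c(0.53, 0, 0)))
  expect_true(residueContact(near, 1, 2))
  far <- pointResidueSystem(list(c(0, 0, 0), c(0.55, 0, 0)))
  expect_false(residueContact(far, 1, 2))
  # hydrogens at 0.1 nm while heavy atoms sit at 1 nm: no contact
  hsys <- pointResidueSystem(list(c(0, 0, 0), c(-0.9, 0, 0)), withHydrogen = TRUE)
  # heavy CA atoms 0.9 nm apart, but H of residue 1 (at 0.1,0,0) is only
  # 0.1 nm from nothing heavy; shrink further: move H of res2 next to res1
  x <- hsys@coords[[1]]
  x[4, ] <- c(0.05, 0, 0)     # hydrogen of residue 2 right next to residue 1
  hsys@coords <- list(x)
  expect_false(residueContact(hsys, 1, 2))
  # symmetry for every subset
  for (ss in c("heavy", "MC", "SC"))
    expect_identical(
      suppressMessages(residueContact(near, 1, 2, subset = ss)),
      suppressMessages(residueContact(near, 2, 1, subset = ss)))
  # periodic wrap: 0.2 nm apart through the boundary
  wrap <- pointResidueSystem(list(c(0.1, 0, 0), c(4.9, 0, 0)), box = c(5, 5, 5))
  expect_true(residueContact(wrap, 1, 2))
})

test_that("interpeptide contact map equals brute-force enumeration on a 3-chain, 2-frame toy", {
  set.seed(21)
  chains <- lapply(1:3, function(i)
    buildPeptide("SNNFGAILSS", cbind(runif(10, -150, -60), runif(10, -180, 180)),
                 chainId = LETTERS[i]))
  sys <- mergeSystems(chains)
  # second frame: shuffle chains rigidly
  x2 <- sys@coords[[1]]
  top <- topology(sys)
  for (cid in c("A", "B", "C")) {
    sel <- atomSelect(top, paste("chain", cid))
    x2[sel, ] <- sweep(x2[sel, ] %*% t(randomRotationMatrix()), 2,
                       runif(3, 0, 2), "+")
  }
  traj <- new("Trajectory", topology = top, coords = list(sys@coords[[1]], x2),
              box = list(NULL, NULL), time = 0:1)
  for (cls in c("MC-MC", "SC-SC")) {
    cm <- interpeptideContactMap(traj, cls)
    # oracle: plain double loop with minImageDistance
    subset <- if (cls == "MC-MC") "MC" else "SC"
    chainRes <- oligolens:::peptideChainResidues(top)
    L <- 10L
    acc <- matrix(0, L, L)
    for (f in 1:2) {
      x <- traj@coords[[f]]
      for (p in 1:2) for (q in (p + 1):3) {
        for (i in 1:L) for (j in 1:L) {
          ai <- oligolens:::residueSubsetAtoms(top, chainRes[[p]][i], subset)
          aj <- oligolens:::residueSubsetAtoms(top, chainRes[[q]][j], subset)
          if (!length(ai) || !length(aj)) next
          dmin <- Inf
          for (a in ai) for (b in aj)
            dmin <- min(dmin, minImageDistance(x[a, ], x[b, ]))
          if (dmin <= 0.54) {
            acc[i, j] <- acc[i, j] + 1
            acc[j, i] <- acc[j, i] + 1
          }
        }
      }
    }
    oracle <- acc / (2 * 2 * 3)   # frames x orientations x unordered pairs
    expect_equal(unname(contactProbabilities(cm)), oracle, tolerance = 1e-12)
    expect_equal(contactProbabilities(cm), t(contactProbabilities(cm)),
                 tolerance = 1e-12)
  }
})

test_that("contact maps: separated chains give zeros; sheet oligomer is diagonal-dominant", {
  ch1 <- buildPeptide("SNNFGAILSS", chainId = "A")
  ch2 <- buildPeptide("SNNFGAILSS", chainId = "B")
  ch2@coords <- list(sweep(ch2@coords[[1]], 2, c(5, 5, 5), "+"))
  apart <- mergeSystems(list(ch1, ch2))
  cm <- interpeptideContactMap(apart, "MC-MC")
  expect_true(all(contactProbabilities(cm) == 0))
  oct <- buildSheetOligomer(8)
  cmo <- interpeptideContactMap(oct, "MC-MC")
  p <- contactProbabilities(cmo)
  expect_gt(mean(diag(p)), mean(p[abs(row(p) - col(p)) > 2]))
})

test_that("hydrogen-bond detection applies both geometric criteria strictly", {
  yes <- hbondToy(D = c(0, 0, 0), H = c(0.1, 0, 0), A = c(0.33, 0, 0))
  hb <- detectHBonds(yes)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distanceDA, 0.33, tolerance = 1e-12)
  expect_equal(hb$angleDHA, 180, tolerance = 1e-9)
  # distance criterion: 0.36 nm fails
  no1 <- hbondToy(D = c(0, 0, 0), H = c(0.1, 0, 0), A = c(0.36, 0, 0))
  expect_equal(nrow(detectHBonds(no1)), 0L)
  # angle criterion: displace H so the D-H-A angle is 149 degrees
  makeAngled <- function(target) {
    d <- c(0, 0, 0); a <- c(0.33, 0, 0)
    th <- (180 - target) * pi / 180
    # H at 0.1 nm from D, rotated off the D-A axis until angle(D,H,A)=target
    f <- function(phi) {
      h <- 0.1 * c(cos(phi), sin(phi), 0)
      u <- d - h; v <- a - h
      acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi - target
    }
    phi <- uniroot(f, c(1e-6, pi / 2))$root
    hbondToy(d, 0.1 * c(cos(phi), sin(phi), 0), a)
  }
  expect_equal(nrow(detectHBonds(makeAngled(149))), 0L)
  expect_equal(nrow(detectHBonds(makeAngled(151))), 1L)
})

test_that("hydrogen bonds are invariant under rigid motion and subsets of contacts", {
  dimer <- buildSheetOligomer(2)
  hb0 <- detectHBonds(dimer)
  expect_gt(nrow(hb0), 0)
  set.seed(13)
  moved <- applyRigidMotion(dimer, randomRotationMatrix(), rnorm(3))
  hb1 <- detectHBonds(moved)
  expect_equal(hb1[c("donorHeavy", "acceptor", "class")],
               hb0[c("donorHeavy", "acceptor", "class")])
  expect_equal(hb1$distanceDA, hb0$distanceDA, tolerance = 1e-9)
  # every detected bond is also a heavy-atom contact at 0.35 nm
  for (k in seq_len(nrow(hb0)))
    expect_true(residueContact(dimer, hb0$donorRes[k], hb0$acceptorRes[k],
                               cutoff = 0.35))
})

test_that("contact probability is monotone in the cutoff", {
  oct <- buildSheetOligomer(4)
  p1 <- contactProbabilities(interpeptideContactMap(oct, "SC-SC", cutoff = 0.54))
  p2 <- contactProbabilities(interpeptideContactMap(oct, "SC-SC", cutoff = 0.45))
  expect_true(all(p2 <= p1 + 1e-12))
})

test_that("per-frame hydrogen-bond count PDF is a normalized two-state mixture", {
  dimer <- buildSheetOligomer(2)
  nearX <- dimer@coords[[1]]
  top <- topology(dimer)
  selB <- atomSelect(top, "chain B")
  farX <- nearX
  farX[selB, ] <- sweep(farX[selB, ], 2, c(4, 4, 4), "+")
  # 6 bonded frames, 4 separated frames
  traj <- new("Trajectory", topology = top,
              coords = c(rep(list(nearX), 6), rep(list(farX), 4)),
              box = rep(list(NULL), 10), time = 0:9)
  hb <- detectHBonds(traj)
  chainOf <- vapply(residues(top), function(r) r$chainId, "")
  nMC <- sum(hb$frame == 1 & hb$class == "MC-MC" &
             chainOf[hb$donorRes] != chainOf[hb$acceptorRes])
  expect_gt(nMC, 0)
  p <- hbondCountPdf(traj, "MC")
  expect_equal(sum(p$probability), 1, tolerance = 1e-12)
  expect_equal(p$probability[p$count == nMC], 0.6, tolerance = 1e-12)
  expect_equal(p$probability[p$count == 0], 0.4, tolerance = 1e-12)
  # ensemble with no bonds anywhere: point mass at zero
  none <- new("Trajectory", topology = top, coords = rep(list(farX), 3),
              box = rep(list(NULL), 3), time = 0:2)
  p0 <- hbondCountPdf(none, "MC")
  expect_equal(p0, data.frame(count = 0L, probability = 1))
})

test_that("ligand binding probability matches brute-force enumeration", {
  set.seed(31)
  ch <- lapply(1:2, function(i)
    buildPeptide("SNNFGAILSS", chainId = LETTERS[i]))
  ch[[2]]@coords <- list(sweep(ch[[2]]@coords[[1]], 2, c(3, 0, 0), "+"))
  ligs <- lapply(1:2, function(i) buildLigand())
  sys <- mergeSystems(c(ch, ligs))
  top <- topology(sys)
  frames <- lapply(1:3, function(f) {
    x <- sys@coords[[1]]
    for (cid in chains(top)$id[chains(top)$kind == "ligand"]) {
      sel <- atomSelect(top, paste("chain", cid))
      x[sel, ] <- sweep(x[sel, ] %*% t(randomRotationMatrix()), 2,
                        runif(3, 0, 3), "+")
    }
    x
  })
  traj <- new("Trajectory", topology = top, coords = frames,
              box = rep(list(NULL), 3), time = 0:2)
  bp <- ligandBindingProbability(traj)
  # oracle
  chainRes <- oligolens:::peptideChainResidues(top)
  ligAtoms <- oligolens:::ligandHeavyAtoms(top)
  hits <- numeric(10)
  for (f in 1:3) for (p in 1:2) for (k in 1:10) {
    ai <- oligolens:::residueSubsetAtoms(top, chainRes[[p]][k], "heavy")
    x <- frames[[f]]
    dmin <- Inf
    for (a in ai) for (b in ligAtoms)
      dmin <- min(dmin, sqrt(sum((x[a, ] - x[b, ])^2)))
    if (dmin <= 0.54) hits[k] <- hits[k] + 1
  }
  expect_equal(bp$probability, hits / 6, tolerance = 1e-12)
  # glued ligand: probability 1/nChains at the anchor residue position
  phe <- ringSelection(top, "chain A and resname PHE")[[1]]
  rg <- ringGeometry(sys@coords[[1]][phe, ])
  lig <- buildLigand()
  glued <- placeLigandStacked(lig, rg, 0, 0.40)
  sys2 <- mergeSystems(c(ch, list(glued)))
  bp2 <- ligandBindingProbability(sys2)
  expect_equal(bp2$probability[bp2$label == "F23"], 0.5, tolerance = 1e-12)
})

test_that("ligand hydrogen-bond profile localizes a constructed backbone bond", {
  ch <- buildPeptide("SNNFGAILSS", chainId = "A")
  top1 <- topology(ch)
  # acceptor: backbone O of N22 (third amino-acid residue)
  res <- oligolens:::peptideChainResidues(top1)[["A"]]
  n22 <- res[3]
  oAt <- residues(top1)[[n22]]$atoms
  oAt <- oAt[atoms(top1)$name[oAt] == "O"][1]
  target <- ch@coords[[1]][oAt, ]
  lig <- buildLigand()
  xl <- lig@coords[[1]]
  nam <- which(atoms(lig)$name == "NAM")
  ham <- which(atoms(lig)$name == "HAM")
  # rotate ligand so NAM->HAM points along +x, then put HAM 0.19 nm from O
  u <- xl[ham, ] - xl[nam, ]; u <- u / sqrt(sum(u^2))
  ax <- c(u[2], -u[1], 0)
  if (sqrt(sum(ax^2)) > 1e-9) {
    R <- oligolens:::rotationAboutAxis(ax / sqrt(sum(ax^2)),
                                       acos(u[3]) * 180 / pi)  # u -> z
  } else R <- diag(3)
  xl <- xl %*% t(R)
  dirDA <- c(0, 0, 1)
  xl <- sweep(xl, 2, xl[nam, ])            # NAM at origin, H along +z
  xl <- sweep(xl, 2, target - 0.29 * dirDA, "+")
  lig@coords <- list(xl)
  sys <- mergeSystems(list(ch, lig))
  hb <- detectHBonds(sys, scope = "peptide-ligand")
  expect_equal(nrow(hb), 1L)
  prof <- ligandHbondProfile(sys)
  expect_equal(prof$mc[prof$label == "N22"], 1)
  expect_equal(sum(prof$mc), 1)
  expect_equal(sum(prof$sc), 0)
  # two-frame variant present in half the frames
  far <- sweep(xl, 2, c(5, 5, 5), "+")
  traj <- new("Trajectory", topology = topology(sys),
              coords = list(sys@coords[[1]],
                            rbind(ch@coords[[1]], far)),
              box = list(NULL, NULL), time = 0:1)
  prof2 <- ligandHbondProfile(traj)
  expect_equal(prof2$mc[prof2$label == "N22"], 0.5)
})

test_that("no-ligand trajectories are rejected by the ligand detectors", {
  tr <- buildPeptide("AG", seqStart = 1)
  expect_error(ligandBindingProbability(tr), "no ligand")
})
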