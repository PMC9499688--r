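test_that("amide hydrogen reconstruction follows the bisector rule", {
  # hand-built context: previous carbonyl C and O, amide N
  Cp <- c(0, 0, 0); Op <- c(0, 0.123, 0); N <- c(0.133, -0.06, 0)
  u1 <- (N - Cp) / sqrt(sum((N - Cp)^2))
  u2 <- (N - Op) / sqrt(sum((N - Op)^2))
  u <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
  expected <- N + 0.10 * u
  got <- oligolens:::amideHydrogenFromContext(N, Cp, Op)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(sqrt(sum((got - N)^2)), 0.10, tolerance = 1e-12)
})

test_that("reconstruction augments missing amide hydrogens and is idempotent", {
  tr <- buildPeptide("SNNFGAILSS")
  # already carries amide hydrogens: unchanged
  same <- reconstructAmideHydrogens(tr)
  expect_equal(nAtoms(same), nAtoms(tr))
  expect_equal(same@coords[[1]], tr@coords[[1]])
  # strip the amide hydrogens via a PDB round trip without H atoms
  path <- tempfile(fileext = ".pdb")
  writeMultiModelPDB(tr, path)
  lines <- readLines(path)
  keep <- !grepl("^ATOM", lines) |
    substr(lines, 77, 78) != " H"
  writeLines(lines[keep], path)
  # side-chain donors whose hydrogen was stripped are disabled with a warning
  ws <- capture_warnings(bare <- readMultiModelPDB(path))
  expect_true(any(grepl("donor disabled", ws)))
  aug <- reconstructAmideHydrogens(bare)
  added <- nAtoms(aug) - nAtoms(bare)
  expect_equal(added, 10L)   # one amide H per amino-acid residue
  # every placed H reproduces the bisector formula, re-evaluated directly
  hNew <- aug@coords[[1]][(nAtoms(bare) + 1):nAtoms(aug), ]
  at <- atoms(bare); x <- bare@coords[[1]]
  for (k in 1:10) {
    ri <- k + 1L                       # amino-acid residues follow the cap
    aIdx <- residues(bare)[[ri]]$atoms
    pIdx <- residues(bare)[[ri - 1L]]$atoms
    N <- x[aIdx[at$name[aIdx] == "N"][1], ]
    Cp <- x[pIdx[at$name[pIdx] == "C"][1], ]
    Op <- x[pIdx[at$name[pIdx] == "O"][1], ]
    u1 <- (N - Cp) / sqrt(sum((N - Cp)^2))
    u2 <- (N - Op) / sqrt(sum((N - Op)^2))
    u <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
    expect_equal(hNew[k, ], N + 0.10 * u, tolerance = 1e-12)
    expect_equal(sqrt(sum((hNew[k, ] - N)^2)), 0.10, tolerance = 1e-12)
  }
  # existing atom indices unchanged
  expect_equal(aug@coords[[1]][1:nAtoms(bare), ], bare@coords[[1]])
  # reconstruction is idempotent on the augmented system
  again <- reconstructAmideHydrogens(aug)
  expect_equal(nAtoms(again), nAtoms(aug))
})

test_that("Kabsch-Sander energy reproduces the published formula arithmetic", {
  # geometry with r_OH=1.9, r_ON=2.9, r_CH=3.0, r_CN=4.0 Angstrom
  toy <- hbondToy(D = c(0, 0, 0), H = c(0.1, 0, 0), A = c(0.29, 0, 0))
  # acceptor O at 0.29; add the carbonyl C at 0.40 on the same axis
  top <- topology(toy)
  atoms2 <- rbind(atoms(top), data.frame(
    serial = 4L, name = "C", element = "C", resIndex = 2L, isHydrogen = FALSE,
    mass = 12.011, vdw = 0.17, stringsAsFactors = FALSE))
  res2 <- residues(top)
  res2[[2]]$atoms <- c(3L, 4L)
  res2[[2]]$backbone <- c(3L, 4L)
  top2 <- new("Topology", atoms = atoms2, residues = res2, chains = chains(top))
  tr <- new("Trajectory", topology = top2,
            coords = list(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.29, 0, 0),
                                c(0.40, 0, 0))),
            box = list(NULL), time = 0)
  e <- kabschSanderEnergy(tr, donorRes = 1, acceptorRes = 2)
  expect_equal(e, 27.888 * (1 / 2.9 + 1 / 3.0 - 1 / 1.9 - 1 / 4.0),
               tolerance = 1e-9)
  expect_lt(e, -0.5)   # assigned as a backbone hydrogen bond
  # O and C each equidistant from N and H: exact cancellation
  expect_equal(oligolens:::ksEnergy(N = c(0, 0, 0), H = c(0.1, 0, 0),
                                    C = c(0.05, 0.35, 0), O = c(0.05, 0.2, 0)),
               0, tolerance = 1e-12)
  # distant pair: negligible energy
  farToy <- oligolens:::ksEnergy(c(0, 0, 0), c(0.1, 0, 0),
                                 c(2, 0, 0), c(2.12, 0, 0))
  expect_lt(abs(farToy), 0.5)
  expect_error(kabschSanderEnergy(tr, 1, 1), "distinct")
})

test_that("secondary structure: helix, parallel sheet, lone strand", {
  helix <- buildPeptide(strrep("A", 12), phiPsi = c(-57, -47), seqStart = 1)
  ssH <- ssCodes(assignSecondaryStructure(helix))[1, ]
  expect_true(all(ssH[3:10] == "H"))
  sheet <- buildSheetOligomer(2)
  ssE <- ssCodes(assignSecondaryStructure(sheet))[1, ]
  expect_true(all(ssE[c(3:8, 13:18)] == "E"))
  lone <- buildPeptide("SNNFGAILSS", phiPsi = c(-116, 111))
  ssL <- ssCodes(assignSecondaryStructure(lone))[1, ]
  expect_false(any(ssL %in% c("E", "B")))
  # extended backbone cannot satisfy helix turns either
  expect_false(any(ssL == "H"))
})

test_that("secondary structure is invariant under rigid motion and partitions categories", {
  sheet <- buildSheetOligomer(3)
  set.seed(17)
  moved <- applyRigidMotion(sheet, randomRotationMatrix(), rnorm(3, 0, 2))
  expect_identical(ssCodes(assignSecondaryStructure(sheet)),
                   ssCodes(assignSecondaryStructure(moved)))
  ss <- assignSecondaryStructure(sheet)
  cats <- ssCategories(ss)
  expect_true(all(cats %in% oligolens:::ssCategoryNames()))
  pop <- ssPopulation(ss)
  expect_equal(sum(pop$fraction), 1, tolerance = 1e-12)
  perRes <- ssPopulation(ss, perResidue = TRUE)
  sums <- tapply(perRes$fraction, perRes$label, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("an all-coil assignment reports pure coil", {
  codes <- matrix("C", 5, 4)
  ss <- new("SecondaryStructure", codes = codes, residueIndex = 1:4,
            labels = paste0("G", 1:4))
  pop <- ssPopulation(ss)
  expect_equal(pop$fraction[pop$category == "coil"], 1)
  expect_equal(sum(pop$fraction), 1)
})

test_that("SASA: analytic sphere, additivity, two-sphere cap formula", {
  single <- pointResidueSystem(list(c(0, 0, 0)))
  s1 <- shrakeRupleySasa(single, selection = 1L)
  exact <- 4 * pi * 0.31^2
  expect_lt(abs(s1$total - exact) / exact, 0.01)
  pairFar <- pointResidueSystem(list(c(0, 0, 0), c(5, 0, 0)))
  s2 <- shrakeRupleySasa(pairFar, selection = 1:2)
  expect_equal(s2$total, 2 * s1$total, tolerance = 1e-12)
  expect_equal(s2$perResidue, setNames(c(s1$total, s1$total), c("1", "2")),
               tolerance = 1e-12)
  # overlapping equal spheres at distance d: exposed area per sphere is
  # 4 pi R^2 - 2 pi R (R - d/2)
  d <- 0.35
  R <- 0.31
  pairNear <- pointResidueSystem(list(c(0, 0, 0), c(d, 0, 0)))
  s3 <- shrakeRupleySasa(pairNear, selection = 1:2)
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  expect_lt(abs(s3$total - analytic) / analytic, 0.02)
})

test_that("SASA converges with point count and decreases on approach", {
  d <- 0.35; R <- 0.31
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  pairNear <- pointResidueSystem(list(c(0, 0, 0), c(d, 0, 0)))
  e240 <- abs(shrakeRupleySasa(pairNear, selection = 1:2,
                               nPoints = 240)$total - analytic)
  e4000 <- abs(shrakeRupleySasa(pairNear, selection = 1:2,
                                nPoints = 4000)$total - analytic)
  expect_lt(e4000, e240)
  dists <- c(0.6, 0.5, 0.4, 0.3, 0.2)
  areas <- vapply(dists, function(dd)
    shrakeRupleySasa(pointResidueSystem(list(c(0, 0, 0), c(dd, 0, 0))),
                     selection = 1:2)$total, 0)
  expect_true(all(diff(areas) < 1e-6))
})

test_that("SASA is invariant under rigid motion", {
  tr <- buildSheetOligomer(2)
  s0 <- shrakeRupleySasa(tr)
  set.seed(23)
  moved <- applyRigidMotion(tr, randomRotationMatrix(), rnorm(3))
  s1 <- shrakeRupleySasa(moved)
  expect_lt(abs(s1$total - s0$total) / s0$total, 0.01)
})

test_that("reference DSSP implementation agrees on generated fixtures", {
  fixtures <- list(
    helix = buildPeptide(strrep("A", 12), phiPsi = c(-57, -47), seqStart = 1),
    parallel = buildSheetOligomer(2),
    antiparallel = buildSheetOligomer(2, registry = "antiparallel"),
    sheet4 = buildSheetOligomer(4),
    extended = buildPeptide("SNNFGAILSS", phiPsi = c(-116, 111)))
  agree <- 0L; total <- 0L
  for (fx in fixtures) {
    mine <- ssCodes(assignSecondaryStructure(fx))[1, ]
    ref <- mdtrajDssp(fx)[[1]]
    expect_length(ref, length(mine))
    agree <- agree + sum(mine == ref)
    total <- total + length(mine)
  }
  expect_gte(agree / total, 0.95)
})
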