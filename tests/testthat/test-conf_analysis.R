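# Strain-analysis protocol: torsion sampling, global search, Pareto
# retention, alignment, strain statistics.

test_that("polar-hydrogen sampling enumerates OH/NH rotor combinations", {
  methane <- embedSmiles("C")
  expect_length(samplePolarHTorsions(methane), 1L)

  meoh <- embedSmiles("CO")
  at <- atomTable(meoh)
  variants <- samplePolarHTorsions(meoh, increment = 120)
  expect_length(variants, 3L)
  # variants differ only in the H-O-C-H torsion; heavy atoms untouched
  o <- which(at$elem == "O")
  c1 <- which(at$elem == "C")
  adj <- sdpipe:::adjacency(meoh)
  oh <- intersect(adj[[o]], which(at$elem == "H"))
  ch <- intersect(adj[[c1]], which(at$elem == "H"))[1L]
  angles <- sort(vapply(variants, function(v)
    round(getTorsion(v, oh, o, c1, ch)), 0))
  expect_equal(diff(angles), c(120, 120), tolerance = 0.01)
  heavy <- which(at$elem != "H")
  for (v in variants)
    expect_lt(max(abs(v[heavy, ] - coords(meoh)[heavy, ])), 1e-9)

  glycol <- embedSmiles("OCCO")
  expect_length(samplePolarHTorsions(glycol, increment = 120), 9L)
})

test_that("rigid benzene: global minimum equals the local minimum", {
  bz <- embedSmiles("c1ccccc1")
  ff <- ffSetup(bz)
  gs <- globalMinimumSearch(bz, coords(bz), ff = ff)
  loc <- minimizeConformer(bz, ff = ff)
  expect_lt(abs(confEnergy(gs$globalMin) - confEnergy(loc)), 0.01)
  expect_true(all(vapply(gs$ensemble, confEnergy, 0) >=
                    confEnergy(gs$globalMin) - 1e-9))
})

test_that("global search finds the anti rotamer from an eclipsed butane start", {
  b <- embedSmiles("CCCC")
  eclipsed <- setTorsion(b, coords(b), 1L, 2L, 3L, 4L, 0)
  gs <- globalMinimumSearch(b, eclipsed)
  expect_lt(abs(abs(getTorsion(gs$globalMin@coords, 1L, 2L, 3L, 4L)) - 180),
            5)
})

test_that("pareto filter matches the worked example and handles ties", {
  cands <- list(fakeConformer(0.5, 2.0), fakeConformer(0.6, 1.0),
                fakeConformer(0.7, 3.0))
  kept <- paretoFilter(cands)
  expect_identical(vapply(kept, confRMSD, 0), c(0.5, 0.6))

  expect_length(paretoFilter(list(fakeConformer(1, 1))), 1L)
  # an exact duplicate of a retained conformer is dropped
  expect_length(paretoFilter(list(fakeConformer(1, 1)),
                             list(fakeConformer(1, 1))), 0L)
})

test_that("pareto filter equals the quadratic domination oracle on random sets", {
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(1:200, 1L)
    m <- sample(0:20, 1L)
    # duplicated grid values exercise the tie rules
    cands <- lapply(seq_len(n), function(i)
      fakeConformer(sample(0:20, 1L) / 10, sample(0:20, 1L) / 2))
    ret <- lapply(seq_len(m), function(i)
      fakeConformer(sample(0:20, 1L) / 10, sample(0:20, 1L) / 2))
    kept <- paretoFilter(cands, ret)
    oracle <- bruteParetoKeep(cands, ret)
    expect_identical(vapply(kept, confRMSD, 0),
                     vapply(cands[oracle], confRMSD, 0),
                     label = sprintf("trial %d", trial))
    expect_identical(vapply(kept, confEnergy, 0),
                     vapply(cands[oracle], confEnergy, 0))
  }
})

test_that("alignment recovers rigid motions and respects symmetry", {
  asp <- embedSmiles("CC(=O)Oc1ccccc1C(=O)O")
  x <- coords(asp)
  fit0 <- alignConformer(asp, x, x)
  expect_lt(fit0$rmsd, 1e-9)

  rot <- sdpipe:::rotationMatrix(c(0, 0, 1), pi / 2)
  moved <- sweep(x %*% t(rot), 2L, c(3, -1, 2), `+`)
  fit <- alignConformer(asp, moved, x)
  expect_lt(fit$rmsd, 1e-6)
  # idempotent: aligning the aligned coordinates changes nothing
  fit2 <- alignConformer(asp, fit$coords, x)
  expect_lt(abs(fit2$rmsd - fit$rmsd), 1e-9)

  # benzene relabeled by a ring rotation maps onto itself even as a
  # rigid motion (the hexagon is geometrically symmetric), so both
  # modes recover RMSD ~ 0
  bz <- embedSmiles("c1ccccc1")
  at <- atomTable(bz)
  ring <- which(at$elem == "C")
  hs <- vapply(ring, function(i)
    intersect(sdpipe:::adjacency(bz)[[i]], which(at$elem == "H")), 0L)
  perm <- seq_len(atomCount(bz))
  perm[ring] <- ring[c(2:6, 1)]  # rotate ring labels by one position
  perm[hs] <- hs[c(2:6, 1)]
  relabeled <- coords(bz)[perm, ]
  expect_lt(alignConformer(bz, relabeled, coords(bz))$rmsd, 1e-6)

  # swapping the two topologically equivalent methyls of
  # 2-methylbutane is NOT a rigid motion: only the automorphism
  # search recovers a near-zero RMSD
  mb <- embedSmiles("CC(C)CC")
  swap <- seq_len(atomCount(mb))
  swap[c(1L, 3L)] <- c(3L, 1L)  # the two methyl carbons on C2
  relabeled2 <- coords(mb)[swap, ]
  expect_lt(alignConformer(mb, relabeled2, coords(mb))$rmsd, 1e-6)
  expect_gt(alignConformer(mb, relabeled2, coords(mb),
                           symmetry = FALSE)$rmsd, 0.1)
})

test_that("atom-count mismatches are rejected", {
  expect_error(alignConformer(embedSmiles("CO"), matrix(0, 3, 3),
                              matrix(0, 6, 3)), "differ")
})

test_that("the default profile has the expected conformer roles", {
  pose <- makeStrainedPose("CC(=O)Oc1ccccc1C(=O)O", seed = 3)
  profile <- analyzeStrain(pose)
  roles <- vapply(profileConformers(profile), confRole, "")
  expect_identical(sum(roles == "constrained"), 4L)
  expect_identical(sum(roles == "input"), 1L)
  expect_identical(sum(roles == "local_min"), 1L)
  expect_identical(sum(roles == "global_min"), 1L)
  radii <- vapply(profileConformers(profile), confRadius, 0)
  expect_identical(sort(radii[roles == "constrained"]),
                   c(0.2, 0.6, 1.0, 1.4))
  input <- profileConformers(profile)[[which(roles == "input")]]
  expect_identical(confRMSD(input), 0)
  expect_true(all(vapply(profileConformers(profile), confEnergy, 0) >=
                    globalMinEnergy(profile) - 1e-9))
})

test_that("a pre-minimized rigid input yields a flat, unstrained profile", {
  bz <- embedSmiles("c1ccccc1")
  profile <- analyzeStrain(bz)
  en <- vapply(profileConformers(profile), confEnergy, 0)
  expect_lt(max(en) - globalMinEnergy(profile), 0.1)
  expect_lt(strainAtThreshold(profile, 0.4), 0.1)
  expect_false(flagStrained(profile))
})

test_that("strain-at-threshold is monotone and grounded at its extremes", {
  pose <- makeStrainedPose("CC(C)Cc1ccc(C(C)C(=O)O)cc1", seed = 4)
  profile <- analyzeStrain(pose)
  grid <- seq(0.2, 1.0, by = 0.1)
  s <- vapply(grid, function(t) strainAtThreshold(profile, t), 0)
  expect_true(all(diff(s) <= 1e-9))
  # at zero relaxation: the input single-point relative to global min
  roles <- vapply(profileConformers(profile), confRole, "")
  inputE <- confEnergy(profileConformers(profile)[[which(roles == "input")]])
  expect_equal(strainAtThreshold(profile, 0),
               inputE - globalMinEnergy(profile), tolerance = 1e-9)
  # once the global minimum qualifies, strain is exactly zero
  gmRMSD <- confRMSD(profileConformers(profile)[[which(roles ==
                                                         "global_min")]])
  expect_identical(strainAtThreshold(profile, gmRMSD + 0.01), 0)
})

test_that("flagging uses a strict threshold", {
  mk <- function(strain) {
    base <- fakeConformer(0, strain)
    base@role <- "input"
    gm <- fakeConformer(1.0, 0)  # global min outside the 0.4 A allowance
    gm@role <- "global_min"
    new("StrainProfile", mol = toyRecord(), conformers = list(base, gm),
        globalMinEnergy = 0)
  }
  expect_false(flagStrained(mk(3.9)))
  expect_false(flagStrained(mk(4.0)))  # "exceed" means strictly greater
  expect_true(flagStrained(mk(4.1)))
})

test_that("eclipsed-butane strain agrees with a direct torsion-scan oracle", {
  b <- embedSmiles("CCCC")
  ff <- ffSetup(b)
  eclipsed <- setTorsion(b, coords(b), 1L, 2L, 3L, 4L, 0)
  rec <- b
  coords(rec) <- eclipsed
  profile <- analyzeStrain(rec)
  strain <- strainAtThreshold(profile, 0.05)
  # oracle: single-point of the input minus the best of 36 scan starts
  scanE <- vapply(seq(0, 350, by = 10), function(a)
    ffMinimize(ff, setTorsion(b, coords(b), 1L, 2L, 3L, 4L, a))$energy, 0)
  oracle <- ffEnergy(ff, eclipsed) - min(scanE)
  expect_equal(strain, oracle, tolerance = 0.3)
})
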