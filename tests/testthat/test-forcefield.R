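# Force-field correctness: analytic gradients, torsional minima,
# constrained minimization.

test_that("analytic gradients match finite differences", {
  pose <- makeStrainedPose("CC(=O)Nc1ccccc1", seed = 9, sigma = 0.2)
  ff <- ffSetup(pose)
  x0 <- coords(pose)
  ref <- x0 + 0.15
  got <- sdpipe:::ffCall(ff, x0, ref = ref, radius = 0.05, rk = 100)
  g <- got$gradient
  h <- 1e-6
  num <- matrix(0, nrow(x0), 3L)
  for (i in seq_len(nrow(x0))) for (c in 1:3) {
    xp <- x0; xp[i, c] <- xp[i, c] + h
    xm <- x0; xm[i, c] <- xm[i, c] - h
    ep <- sdpipe:::ffCall(ff, xp, ref = ref, radius = 0.05, rk = 100)
    em <- sdpipe:::ffCall(ff, xm, ref = ref, radius = 0.05, rk = 100)
    num[i, c] <- (ep$energy + ep$restraint - em$energy - em$restraint) /
      (2 * h)
  }
  expect_lt(max(abs(g - num)), 1e-4)
})

test_that("minimization is monotone and a converged geometry is a fixed point", {
  pose <- makeStrainedPose("CCCC", seed = 2, sigma = 0.2)
  ff <- ffSetup(pose)
  e0 <- ffEnergy(ff, coords(pose))
  res <- ffMinimize(ff, coords(pose))
  expect_lt(res$energy, e0)
  again <- ffMinimize(ff, res$coords)
  expect_lt(abs(again$energy - res$energy), 1e-4)
  expect_lt(sdpipe:::plainRMSD(again$coords, res$coords), 0.05)
})

test_that("eclipsed ethane relaxes to a staggered rotamer", {
  e <- embedSmiles("CC")
  at <- atomTable(e)
  h1 <- which(at$elem == "H")[1L]
  h2 <- which(at$elem == "H")[4L]
  # exact eclipse is a saddle point; start a nudge away from it
  nearEclipsed <- setTorsion(e, coords(e), h1, 1L, 2L, h2, 10)
  res <- ffMinimize(ffSetup(e), nearEclipsed)
  final <- getTorsion(res$coords, h1, 1L, 2L, h2)
  expect_lt(min(abs(abs(final) - 60), abs(abs(final) - 180)), 2)
})

test_that("butane: no rotamer beats the anti minimum (10-degree scan oracle)", {
  b <- embedSmiles("CCCC")
  ff <- ffSetup(b)
  # independent exhaustive scan: minimize from every 10-degree start
  scan <- lapply(seq(0, 350, by = 10), function(a)
    ffMinimize(ff, setTorsion(b, coords(b), 1L, 2L, 3L, 4L, a)))
  scanE <- vapply(scan, `[[`, 0, "energy")
  finals <- vapply(scan, function(r)
    getTorsion(r$coords, 1L, 2L, 3L, 4L), 0)
  best <- which.min(scanE)
  expect_lt(abs(abs(finals[best]) - 180), 5)  # global rotamer is anti
  gauche <- abs(finals) > 50 & abs(finals) < 80
  expect_true(any(gauche))
  expect_gt(min(scanE[gauche]), scanE[best] + 0.3)  # gauche penalty
})

test_that("flat-bottom restraints bound relaxation and vanish at large radius", {
  pose <- makeStrainedPose("CC(=O)Oc1ccccc1C(=O)O", seed = 5, sigma = 0.15)
  ff <- ffSetup(pose)
  un <- minimizeConformer(pose, ff = ff)
  tight <- constrainedMinimize(pose, radius = 0.01, ff = ff)
  expect_lt(confRMSD(tight), 0.1)
  wide <- constrainedMinimize(pose, radius = 100, ff = ff)
  expect_lt(abs(confEnergy(wide) - confEnergy(un)), 0.05)
  # nested feasible regions: energies non-increasing with radius, and
  # never below the unconstrained minimum
  es <- vapply(c(0.2, 0.6, 1.0, 1.4), function(r)
    confEnergy(constrainedMinimize(pose, radius = r, ff = ff)), 0)
  expect_true(all(diff(es) <= 0.05))
  expect_true(all(es >= confEnergy(un) - 0.05))
})

test_that("force-field setup rejects unusable molecules", {
  bare <- sdRecord(title = "bareC",
                   atoms = data.frame(elem = "C", x = 0, y = 0, z = 0,
                                      charge = 0L))
  expect_error(ffSetup(bare), "implicit hydrogens")
  exotic <- sdRecord(title = "U",
                     atoms = data.frame(elem = "U", x = 0, y = 0, z = 0,
                                        charge = 0L))
  expect_error(ffSetup(exotic), "unparameterized|unknown")
  expect_error(ffSetup(sdRecord()), "empty")
})
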