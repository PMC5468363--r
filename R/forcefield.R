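# Force-field setup and minimization.
#
# A compact gas-phase molecular-mechanics force field: harmonic bond
# stretches, cosine-harmonic angle bends, periodic torsions keyed on
# the hybridization of the central bond, and Lennard-Jones
# interactions (UFF van der Waals parameters) for atom pairs three or
# more bonds apart, with the 1-4 pairs scaled by 0.5. No explicit
# electrostatics and no solvation term: energies are comparable within
# a molecule (conformational strain), not across molecules.

# UFF vdW parameters: x = vdW distance (A), d = well depth (kcal/mol)
UFF_VDW_X <- c(H = 2.886, B = 4.083, C = 3.851, N = 3.660, O = 3.500,
               F = 3.364, Si = 4.295, P = 4.147, S = 4.035, Cl = 3.947,
               Br = 4.189, I = 4.500, Na = 2.983, K = 3.812)
UFF_VDW_D <- c(H = 0.044, B = 0.180, C = 0.105, N = 0.069, O = 0.060,
               F = 0.050, Si = 0.402, P = 0.305, S = 0.274, Cl = 0.227,
               Br = 0.251, I = 0.339, Na = 0.030, K = 0.035)

# single-bond covalent radii (A)
COV_RADIUS <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
                Br = 1.20, I = 1.39, Na = 1.66, K = 2.03)

BOND_ORDER_FACTOR <- c(`1` = 1.00, `2` = 0.89, `3` = 0.82, `4` = 0.93)

# per-atom hybridization: 1 = sp, 2 = sp2, 3 = sp3
hybridization <- function(rec) {
  n <- atomCount(rec)
  hyb <- rep.int(3L, n)
  b <- bondTable(rec)
  ndouble <- integer(n)
  for (i in seq_len(nrow(b))) {
    o <- b$order[i]
    for (a in c(b$a1[i], b$a2[i])) {
      if (o == 2L) ndouble[a] <- ndouble[a] + 1L
      if (o %in% c(2L, 4L) && hyb[a] == 3L) hyb[a] <- 2L
      if (o == 3L) hyb[a] <- 1L
    }
  }
  hyb[ndouble >= 2L] <- 1L
  hyb
}

#' Build force-field terms for a molecule
#'
#' The molecule must carry explicit hydrogens (no implicit hydrogen
#' may remain) and all elements must be parameterized.
#'
#' @param rec an [SDRecord-class] with 3D coordinates.
#' @return An opaque term list consumed by [ffEnergy()] and
#'   [ffMinimize()].
#' @export
ffSetup <- function(rec) {
  at <- atomTable(rec)
  n <- nrow(at)
  if (n == 0L) stop("cannot set up a force field for an empty molecule")
  if (sum(implicitHCounts(rec)) > 0L)
    stop("molecule has implicit hydrogens; explicit hydrogens required ",
         "for minimization")
  bad <- !at$elem %in% names(UFF_VDW_X)
  if (any(bad))
    stop("unparameterized atom(s): ",
         paste(sprintf("%d (%s)", which(bad), at$elem[bad]), collapse = ", "))
  b <- bondTable(rec)
  adj <- adjacency(rec)
  hyb <- hybridization(rec)

  r0 <- (COV_RADIUS[at$elem[b$a1]] + COV_RADIUS[at$elem[b$a2]]) *
    BOND_ORDER_FACTOR[as.character(b$order)]
  bonds <- list(idx = cbind(b$a1, b$a2), r0 = unname(r0),
                k = rep.int(600, nrow(b)))

  # angles at every atom with >= 2 neighbors
  ai <- list(); acos0 <- numeric(); ak <- numeric()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    th0 <- if (hyb[j] == 1L) 180 else if (hyb[j] == 2L) 120 else
      if (at$elem[j] %in% c("O", "S") && length(nb) == 2L) 104.5 else 109.47
    prs <- utils::combn(nb, 2L)
    for (p in seq_len(ncol(prs))) {
      ai[[length(ai) + 1L]] <- c(prs[1L, p], j, prs[2L, p])
      acos0[[length(acos0) + 1L]] <- cos(th0 * pi / 180)
      ak[[length(ak) + 1L]] <- 60
    }
  }
  angles <- list(idx = if (length(ai)) do.call(rbind, ai) else
    matrix(integer(), 0L, 3L), cos0 = acos0, k = ak)

  # torsions around every bond between non-sp atoms with >= 2 neighbors
  ti <- list(); tv <- numeric(); tn <- numeric(); tp <- numeric()
  for (i in seq_len(nrow(b))) {
    j <- b$a1[i]; k <- b$a2[i]
    if (hyb[j] == 1L || hyb[k] == 1L) next
    js <- setdiff(adj[[j]], k); ks <- setdiff(adj[[k]], j)
    if (length(js) == 0L || length(ks) == 0L) next
    sp2 <- hyb[j] == 2L && hyb[k] == 2L
    mixed <- xor(hyb[j] == 2L, hyb[k] == 2L)
    for (a in js) for (d in ks) {
      if (a == d) next  # three-membered ring
      ti[[length(ti) + 1L]] <- c(a, j, k, d)
      if (sp2) {        # planar: minima at 0 and 180 degrees
        tv[[length(tv) + 1L]] <- 2.5; tn[[length(tn) + 1L]] <- 2
        tp[[length(tp) + 1L]] <- pi
      } else if (mixed) {
        tv[[length(tv) + 1L]] <- 0.08; tn[[length(tn) + 1L]] <- 6
        tp[[length(tp) + 1L]] <- 0
      } else {          # sp3-sp3: staggered minima
        tv[[length(tv) + 1L]] <- 0.16; tn[[length(tn) + 1L]] <- 3
        tp[[length(tp) + 1L]] <- 0
      }
    }
  }
  torsions <- list(idx = if (length(ti)) do.call(rbind, ti) else
    matrix(integer(), 0L, 4L), v = tv, n = tn, p = tp)

  # nonbonded pairs: graph distance >= 3 (1-4 scaled 0.5)
  vi <- list(); vx <- numeric(); vd <- numeric(); vs <- numeric()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      d <- graphDistances(adj, i)
      for (j in (i + 1L):n) {
        dij <- d[j]
        if (!is.na(dij) && dij < 3L) next
        vi[[length(vi) + 1L]] <- c(i, j)
        vx[[length(vx) + 1L]] <- sqrt(UFF_VDW_X[[at$elem[i]]] *
                                        UFF_VDW_X[[at$elem[j]]])
        vd[[length(vd) + 1L]] <- sqrt(UFF_VDW_D[[at$elem[i]]] *
                                        UFF_VDW_D[[at$elem[j]]])
        vs[[length(vs) + 1L]] <- if (!is.na(dij) && dij == 3L) 0.5 else 1.0
      }
    }
  }
  vdw <- list(idx = if (length(vi)) do.call(rbind, vi) else
    matrix(integer(), 0L, 2L), x = vx, d = vd, s = vs)

  list(natoms = n, bonds = bonds, angles = angles, torsions = torsions,
       vdw = vdw)
}

ffCall <- function(ff, coords, ref = NULL, radius = 0, rk = 5000) {
  .ff_eval(coords,
           ff$bonds$idx, ff$bonds$r0, ff$bonds$k,
           ff$angles$idx, ff$angles$cos0, ff$angles$k,
           ff$torsions$idx, ff$torsions$v, ff$torsions$n, ff$torsions$p,
           ff$vdw$idx, ff$vdw$x, ff$vdw$d, ff$vdw$s,
           !is.null(ref), if (is.null(ref)) matrix(0, ff$natoms, 3L)
           else ref, radius, rk)
}

#' Force-field single-point energy
#'
#' @param ff term list from [ffSetup()].
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @return Energy in kcal/mol (no restraint contribution).
#' @export
ffEnergy <- function(ff, coords) ffCall(ff, coords)$energy

#' Minimize a geometry
#'
#' L-BFGS-B minimization with analytic gradients, optionally under a
#' per-atom flat-bottom positional restraint toward `ref`: zero
#' penalty within `radius` of the reference position, harmonic
#' (`0.5 * rk * (d - radius)^2`) outside. The reported energy always
#' excludes the restraint term, so energies are comparable across
#' restraint radii.
#'
#' @param ff term list from [ffSetup()].
#' @param coords starting coordinates (n x 3).
#' @param ref reference coordinates for the restraint, or `NULL` for
#'   unconstrained minimization.
#' @param radius flat-bottom radius in Angstrom.
#' @param rk restraint force constant, kcal/mol/A^2.
#' @param maxit maximum L-BFGS-B iterations.
#' @param gradTol target maximum gradient component, kcal/mol/A.
#' @return List with `coords`, `energy` (kcal/mol, force field only),
#'   and `gradMax` (largest absolute gradient component of the total
#'   objective at the solution).
#' @export
ffMinimize <- function(ff, coords, ref = NULL, radius = 0, rk = 5000,
                       maxit = 2000, gradTol = 1e-3) {
  n <- ff$natoms
  # damped steepest-descent warm-up (per-step displacement capped at
  # 0.05 A) so the quasi-Newton stage starts inside the basin of the
  # input geometry rather than leaping across barriers
  x <- matrix(as.numeric(coords), n, 3L)
  ev <- ffCall(ff, x, ref, radius, rk)
  e <- ev$energy + ev$restraint
  step <- 0.05
  for (it in seq_len(60L)) {
    g <- ev$gradient
    gmax <- max(abs(g))
    if (gmax < 1) break
    trial <- x - g * (step / gmax)
    evT <- ffCall(ff, trial, ref, radius, rk)
    eT <- evT$energy + evT$restraint
    if (eT < e) {
      x <- trial; ev <- evT; e <- eT
    } else {
      step <- step / 2
      if (step < 1e-4) break
    }
  }
  fn <- function(par) {
    r <- ffCall(ff, matrix(par, n, 3L), ref, radius, rk)
    r$energy + r$restraint
  }
  gr <- function(par)
    as.numeric(ffCall(ff, matrix(par, n, 3L), ref, radius, rk)$gradient)
  res <- stats::optim(as.numeric(x), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4,
                                     pgtol = gradTol))
  out <- matrix(res$par, n, 3L)
  final <- ffCall(ff, out, ref, radius, rk)
  list(coords = out, energy = final$energy,
       gradMax = max(abs(final$gradient)))
}

#' Unconstrained minimization from a starting pose
#'
#' The minimum reached from the input geometry without restraints:
#' the "local minimum closest to the input" of the strain protocol.
#'
#' @param rec an [SDRecord-class] (explicit hydrogens, 3D).
#' @param start starting coordinates; default the record's own.
#' @param ff optional precomputed [ffSetup()] terms.
#' @return A [Conformer-class] with role `"local_min"`. `rmsdToInput`
#'   is the plain (unaligned) RMSD to `start`.
#' @export
minimizeConformer <- function(rec, start = coords(rec), ff = ffSetup(rec)) {
  res <- ffMinimize(ff, start)
  new("Conformer", coords = res$coords, energy = res$energy,
      rmsdToInput = plainRMSD(res$coords, start), role = "local_min")
}

#' Flat-bottom constrained minimization
#'
#' Minimizes under a per-atom flat-bottom well of the given radius
#' centred on the input coordinates, limiting relaxation away from
#' the input pose. The returned energy excludes the restraint term.
#'
#' @param rec an [SDRecord-class] (explicit hydrogens, 3D).
#' @param inputCoords reference (and starting) coordinates.
#' @param radius flat-bottom radius, Angstrom (> 0).
#' @param rk restraint force constant, kcal/mol/A^2.
#' @param ff optional precomputed [ffSetup()] terms.
#' @return A [Conformer-class] with role `"constrained"` carrying its
#'   radius.
#' @export
constrainedMinimize <- function(rec, inputCoords = coords(rec), radius,
                                rk = 5000, ff = ffSetup(rec)) {
  stopifnot(radius > 0)
  res <- ffMinimize(ff, inputCoords, ref = inputCoords, radius = radius,
                    rk = rk)
  new("Conformer", coords = res$coords, energy = res$energy,
      rmsdToInput = plainRMSD(res$coords, inputCoords),
      role = "constrained", radius = radius)
}
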