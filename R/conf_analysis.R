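# Conformational strain analysis.
#
# Protocol for one 3D input pose:
#   1. single-point energy of the input;
#   2. unconstrained minimization (the local minimum nearest the
#      input);
#   3. flat-bottom constrained minima at increasing radii, tracing the
#      path between input and local minimum;
#   4. global-minimum search: torsion enumeration over rotatable
#      bonds, polar-hydrogen (OH/NH) rotor sampling, minimization of
#      every candidate, argmin over energies;
#   5. retention of ensemble minima that are Pareto-optimal in
#      (RMSD-to-input, energy);
#   6. alignment of everything to the input pose and the
#      strain-at-threshold statistic.

#' @rdname Conformer-accessors
setMethod("confEnergy", "Conformer", function(x) x@energy)
#' @rdname Conformer-accessors
setMethod("confRMSD", "Conformer", function(x) x@rmsdToInput)
#' @rdname Conformer-accessors
setMethod("confRole", "Conformer", function(x) x@role)
#' @rdname Conformer-accessors
setMethod("confRadius", "Conformer", function(x) x@radius)

#' Accessors for Conformer objects
#'
#' @param x a [Conformer-class].
#' @name Conformer-accessors
NULL

setMethod("show", "Conformer", function(object) {
  cat(sprintf("Conformer [%s]%s: E = %.3f kcal/mol, RMSD(input) = %s A\n",
              object@role,
              if (!is.na(object@radius))
                sprintf(" (radius %.1f A)", object@radius) else "",
              object@energy,
              if (is.na(object@rmsdToInput)) "NA" else
                sprintf("%.3f", object@rmsdToInput)))
})

#' @rdname StrainProfile-accessors
setMethod("profileConformers", "StrainProfile", function(x) x@conformers)
#' @rdname StrainProfile-accessors
setMethod("globalMinEnergy", "StrainProfile", function(x) x@globalMinEnergy)

#' Accessors for StrainProfile objects
#'
#' @param x a [StrainProfile-class].
#' @name StrainProfile-accessors
NULL

setMethod("show", "StrainProfile", function(object) {
  cat(sprintf("StrainProfile of '%s': %d conformers, global min %.3f kcal/mol\n",
              sdTitle(object@mol), length(object@conformers),
              object@globalMinEnergy))
  for (cf in object@conformers)
    cat(sprintf("  %-12s dE = %6.2f  RMSD = %5.2f%s\n", cf@role,
                cf@energy - object@globalMinEnergy, cf@rmsdToInput,
                if (!is.na(cf@radius)) sprintf("  (r=%.1f)", cf@radius)
                else ""))
})

# run fn with a private, restored RNG state
withLocalSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fn()
}

# polar-hydrogen rotors: X-A bonds where X is a terminal O/N carrying
# at least one H and A is its only heavy neighbor. Returns a list of
# dihedral specs (i,j,k,l = H, X, A, ref) plus the H set rotated.
polarHRotors <- function(rec) {
  at <- atomTable(rec)
  adj <- adjacency(rec)
  rotors <- list()
  for (x in which(at$elem %in% c("O", "N"))) {
    nb <- adj[[x]]
    hs <- nb[at$elem[nb] == "H"]
    heavies <- nb[at$elem[nb] != "H"]
    if (length(hs) == 0L || length(heavies) != 1L) next
    a <- heavies[[1L]]
    ref <- setdiff(adj[[a]], x)
    if (length(ref) == 0L) next
    rotors[[length(rotors) + 1L]] <-
      list(i = hs[[1L]], j = x, k = a, l = ref[[1L]])
  }
  rotors
}

#' Sample polar-hydrogen (OH/NH) torsions
#'
#' For every terminal O-H / N-H rotor, generates copies of the
#' geometry with the hydrogen(s) rotated in `increment`-degree steps
#' over 360 degrees (the original angle included). Heavy atoms are
#' untouched. Combinations across rotors are enumerated up to a cap of
#' 81 variants.
#'
#' @param rec an [SDRecord-class].
#' @param coordsIn coordinate matrix to sample from (default the
#'   record's).
#' @param increment torsion step, degrees.
#' @param cap maximum number of variants returned.
#' @return A list of coordinate matrices; just `list(coordsIn)` when
#'   the molecule has no polar-hydrogen rotor.
#' @export
samplePolarHTorsions <- function(rec, coordsIn = coords(rec),
                                 increment = 120, cap = 81L) {
  rotors <- polarHRotors(rec)
  if (length(rotors) == 0L) return(list(coordsIn))
  steps <- seq(0, 360 - increment, by = increment)
  grids <- rep(list(steps), length(rotors))
  combos <- as.matrix(expand.grid(grids))
  if (nrow(combos) > cap) combos <- combos[seq_len(cap), , drop = FALSE]
  out <- vector("list", nrow(combos))
  base <- vapply(rotors, function(r)
    getTorsion(coordsIn, r$i, r$j, r$k, r$l), 0)
  for (ci in seq_len(nrow(combos))) {
    cc <- coordsIn
    for (ri in seq_along(rotors)) {
      off <- combos[ci, ri]
      if (off == 0) next
      r <- rotors[[ri]]
      # rotate the X side (X and its hydrogens)
      cc <- setTorsion(rec, cc, r$i, r$j, r$k, r$l, base[ri] + off)
    }
    out[[ci]] <- cc
  }
  out
}

# torsion-grid enumeration over rotatable heavy-atom bonds: saturated
# rotors are driven to the absolute staggered rotamers (-60, 60, 180),
# conjugated sp2-sp2 rotors to 0 and 180, and mixed rotors take
# 120-degree offsets from the input angle; capped with seeded
# sub-sampling.
enumerateTorsionConformers <- function(rec, coordsIn, maxEnsemble = 500,
                                       seed = 42) {
  rb <- rotatableBonds(rec)
  if (nrow(rb) == 0L) return(list(coordsIn))
  adj <- adjacency(rec)
  at <- atomTable(rec)
  hyb <- hybridization(rec)
  rotors <- list()
  for (i in seq_len(nrow(rb))) {
    j <- rb$a1[i]; k <- rb$a2[i]
    js <- setdiff(adj[[j]], k); ks <- setdiff(adj[[k]], j)
    js <- js[order(at$elem[js] == "H")]  # prefer heavy reference atoms
    ks <- ks[order(at$elem[ks] == "H")]
    current <- getTorsion(coordsIn, js[[1L]], j, k, ks[[1L]])
    angles <- if (hyb[j] == 3L && hyb[k] == 3L) c(60, 180, -60) else
      if (hyb[j] == 2L && hyb[k] == 2L) c(0, 180) else
        current + c(0, 120, 240)
    rotors[[length(rotors) + 1L]] <-
      list(i = js[[1L]], j = j, k = k, l = ks[[1L]], angles = angles)
  }
  combos <- as.matrix(expand.grid(lapply(rotors, function(r)
    seq_along(r$angles))))
  if (nrow(combos) > maxEnsemble) {
    keep <- withLocalSeed(seed, function()
      sort(sample.int(nrow(combos), maxEnsemble)))
    combos <- combos[keep, , drop = FALSE]
  }
  out <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    cc <- coordsIn
    for (ri in seq_along(rotors)) {
      r <- rotors[[ri]]
      cc <- setTorsion(rec, cc, r$i, r$j, r$k, r$l,
                       r$angles[[combos[ci, ri]]])
    }
    out[[ci]] <- cc
  }
  out
}

#' Global-minimum search
#'
#' Enumerates accessible conformations by torsion-driving every
#' rotatable bond (120-degree grid; 180 degrees for conjugated
#' bonds), augments each candidate with polar-hydrogen rotor
#' variants, minimizes every candidate plus the input, and selects
#' the lowest-energy minimum. The candidate set is capped at
#' `params@maxEnsemble` geometries by deterministic, seeded
#' sub-sampling, so results are reproducible for a fixed seed.
#'
#' @param rec an [SDRecord-class] (explicit hydrogens, 3D).
#' @param inputCoords input-pose coordinates.
#' @param params a [StrainParams-class].
#' @param ff optional precomputed [ffSetup()] terms.
#' @param threads minimize the ensemble on this many parallel workers.
#' @return A list with `globalMin` (a [Conformer-class], role
#'   `"global_min"`) and `ensemble` (all minimized candidates).
#' @export
globalMinimumSearch <- function(rec, inputCoords = coords(rec),
                                params = strainParams(),
                                ff = ffSetup(rec), threads = 1L) {
  cands <- enumerateTorsionConformers(rec, inputCoords,
                                      maxEnsemble = params@maxEnsemble,
                                      seed = params@seed)
  withH <- list()
  for (cc in cands) {
    vars <- samplePolarHTorsions(rec, cc,
                                 increment = params@polarHIncrement)
    withH <- c(withH, vars)
    if (length(withH) >= params@maxEnsemble) break
  }
  withH <- withH[seq_len(min(length(withH), params@maxEnsemble))]
  withH <- c(list(inputCoords), withH)
  minimizeOne <- function(cc) {
    res <- ffMinimize(ff, cc)
    new("Conformer", coords = res$coords, energy = res$energy,
        rmsdToInput = plainRMSD(res$coords, inputCoords),
        role = "ensemble")
  }
  ensemble <- if (threads > 1L)
    parallel::mclapply(withH, minimizeOne, mc.cores = threads)
  else lapply(withH, minimizeOne)
  err <- vapply(ensemble, inherits, TRUE, "try-error")
  if (any(err)) stop("ensemble minimization failed: ",
                     conditionMessage(attr(ensemble[[which(err)[1L]]],
                                           "condition")))
  energies <- vapply(ensemble, confEnergy, 0)
  gm <- ensemble[[which.min(energies)]]
  gm@role <- "global_min"
  list(globalMin = gm, ensemble = ensemble)
}

#' Pareto-optimal conformer retention
#'
#' Keeps the candidates not dominated in the (RMSD-to-input, energy)
#' plane by any candidate or already-retained conformer. Point `p`
#' dominates `q` when `p` is less than or equal to `q` in both
#' coordinates and strictly smaller in at least one; candidates that
#' exactly duplicate a retained conformer (or an earlier candidate)
#' are dropped.
#'
#' Implemented as a sort-and-sweep over the staircase front; tests
#' compare it against a quadratic pairwise-domination filter.
#'
#' @param candidates list of [Conformer-class] objects (must carry
#'   finite `rmsdToInput`).
#' @param retained list of already-retained conformers.
#' @return The kept subset of `candidates`, in input order.
#' @export
paretoFilter <- function(candidates, retained = list()) {
  if (length(candidates) == 0L) return(list())
  cr <- vapply(candidates, confRMSD, 0)
  ce <- vapply(candidates, confEnergy, 0)
  rr <- vapply(retained, confRMSD, 0)
  re <- vapply(retained, confEnergy, 0)
  x <- c(cr, rr)
  y <- c(ce, re)
  isCand <- c(rep(TRUE, length(cr)), rep(FALSE, length(rr)))
  candIdx <- c(seq_along(cr), rep(NA_integer_, length(rr)))
  ord <- order(x, y, isCand)  # retained first among exact ties
  keep <- logical(length(candidates))
  bestE <- Inf
  lastX <- NA_real_; lastY <- NA_real_
  for (o in ord) {
    if (y[o] >= bestE) next                      # dominated (or duplicate
    if (!is.na(lastX) && x[o] == lastX && y[o] == lastY) next  # of kept)
    if (isCand[o]) keep[candIdx[o]] <- TRUE
    bestE <- y[o]
    lastX <- x[o]; lastY <- y[o]
  }
  candidates[keep]
}

#' Full strain analysis of one input pose
#'
#' Runs the complete protocol and returns the retained profile: the
#' input conformation (single-point energy, RMSD 0), one flat-bottom
#' constrained minimum per radius, the local minimum, the global
#' minimum, and any additional Pareto-optimal ensemble minima. All
#' retained conformers are rigidly aligned to the input
#' (symmetry-corrected heavy-atom RMSD) and `rmsdToInput` is the
#' post-alignment value.
#'
#' @param rec an [SDRecord-class] with explicit hydrogens and 3D
#'   coordinates.
#' @param params a [StrainParams-class].
#' @param threads parallel workers for the ensemble minimization.
#' @return A [StrainProfile-class].
#' @seealso [strainAtThreshold()], [flagStrained()]
#' @export
analyzeStrain <- function(rec, params = strainParams(), threads = 1L) {
  ff <- ffSetup(rec)
  inputCoords <- coords(rec)
  input <- new("Conformer", coords = inputCoords,
               energy = ffEnergy(ff, inputCoords), rmsdToInput = 0,
               role = "input")
  localMin <- minimizeConformer(rec, inputCoords, ff = ff)
  constrained <- lapply(params@radii, function(r)
    constrainedMinimize(rec, inputCoords, radius = r, ff = ff))
  gs <- globalMinimumSearch(rec, inputCoords, params, ff = ff,
                            threads = threads)
  retained <- c(list(input), constrained, list(localMin, gs$globalMin))

  # align retained + candidates to the input pose; recompute RMSD
  alignTo <- function(cf) {
    if (cf@role == "input") return(cf)
    fit <- alignConformer(rec, cf, inputCoords)
    fit$conformer
  }
  retained <- lapply(retained, alignTo)
  cands <- lapply(gs$ensemble, alignTo)
  extra <- paretoFilter(cands, retained)
  for (i in seq_along(extra)) extra[[i]]@role <- "pareto"
  all <- c(retained, extra)
  new("StrainProfile", mol = rec, conformers = all,
      globalMinEnergy = min(vapply(all, confEnergy, 0)))
}

#' Strain at a relaxation threshold
#'
#' The energy of the lowest-energy retained conformation within
#' `maxRmsd` of the input, relative to the global minimum. The input
#' itself qualifies at any threshold (RMSD 0), so the statistic is
#' always defined; it is monotone non-increasing in `maxRmsd`.
#'
#' @param profile a [StrainProfile-class].
#' @param maxRmsd maximum allowed relaxation, Angstrom.
#' @return Strain energy in kcal/mol (>= 0).
#' @export
strainAtThreshold <- function(profile, maxRmsd) {
  en <- vapply(profile@conformers, confEnergy, 0)
  rm <- vapply(profile@conformers, confRMSD, 0)
  min(en[rm <= maxRmsd + 1e-9]) - profile@globalMinEnergy
}

#' Flag a strained pose
#'
#' `TRUE` iff the strain at the configured maximum relaxation
#' (default 0.4 Angstrom) strictly exceeds the configured threshold
#' (default 4 kcal/mol).
#'
#' @param profile a [StrainProfile-class].
#' @param params a [StrainParams-class].
#' @return Logical.
#' @export
flagStrained <- function(profile, params = strainParams()) {
  strainAtThreshold(profile, params@flagRMSD) > params@flagEnergy
}

#' Expand a strain profile into SD records
#'
#' One record per retained conformer, carrying the fields `Role`,
#' `Radius_A` (constrained conformers only), `E_kcal_mol`,
#' `dE_kcal_mol` (relative to the global minimum) and
#' `RMSD_to_input_A`, all numeric values to two decimals.
#'
#' @param profile a [StrainProfile-class].
#' @return A list of [SDRecord-class] objects.
#' @export
profileToRecords <- function(profile) {
  lapply(profile@conformers, function(cf) {
    rec <- profile@mol
    coords(rec) <- cf@coords
    sdField(rec, "Role") <- cf@role
    if (!is.na(cf@radius))
      sdField(rec, "Radius_A") <- sprintf("%.2f", cf@radius)
    sdField(rec, "E_kcal_mol") <- sprintf("%.2f", cf@energy)
    sdField(rec, "dE_kcal_mol") <-
      sprintf("%.2f", cf@energy - profile@globalMinEnergy)
    sdField(rec, "RMSD_to_input_A") <- sprintf("%.2f", cf@rmsdToInput)
    rec
  })
}
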