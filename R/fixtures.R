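# Deterministic test-input generation.
#
# All fixtures are built in code: a pool of small drug-like molecules
# (<= 30 heavy atoms, <= 7 rotatable bonds) is laid out in 2D with the
# OpenBabel structure-diagram generator, lifted into 3D with seeded
# out-of-plane displacements, relaxed with the package force field,
# and serialized with the package writer, so the same seed always
# yields byte-identical files.

#' The fixture molecule pool
#'
#' Named SMILES of small molecules with well-understood behavior
#' (rigid aromatics, classic torsion cases, polar-hydrogen rotors,
#' and a few drug-like structures).
#'
#' @return Named character vector of SMILES.
#' @export
fixtureSmilesPool <- function() {
  c(methane = "C",
    methanol = "CO",
    ethylene_glycol = "OCCO",
    butane = "CCCC",
    benzene = "c1ccccc1",
    pyridine = "c1ccncc1",
    toluene = "Cc1ccccc1",
    acetanilide = "CC(=O)Nc1ccccc1",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    azaindole7 = "c1ccc2[nH]ccc2n1",
    ibuprofen_core = "CC(C)Cc1ccc(C(C)C(=O)O)cc1")
}

# one-per-session cache of embedded pool molecules
fixtureCache <- new.env(parent = emptyenv())

#' Embed a SMILES in 3D
#'
#' Deterministic 3D construction: the OpenBabel structure-diagram
#' generator supplies a 2D layout with explicit hydrogens, the flat
#' geometry is lifted out of the plane with small seeded Gaussian
#' z-displacements (seed derived from the SMILES text), and the
#' result is relaxed with the package force field. The same SMILES
#' always yields the same coordinates.
#'
#' @param smiles SMILES string.
#' @param title record title.
#' @param minimize relax with the package force field (default
#'   `TRUE`; the raw lifted layout is rarely useful).
#' @return An [SDRecord-class] with 3D coordinates and explicit
#'   hydrogens.
#' @export
embedSmiles <- function(smiles, title = smiles, minimize = TRUE) {
  key <- paste0(smiles, "\r", minimize)
  if (!is.null(fixtureCache[[key]])) {
    rec <- fixtureCache[[key]]
    sdTitle(rec) <- title
    return(rec)
  }
  out <- suppressWarnings(system2("obabel",
    c(shQuote(paste0("-:", smiles)), "-h", "--gen2d", "-osdf"),
    stdout = TRUE, stderr = FALSE))
  rec <- tryCatch(streamCollect(readSD(out), n = 1L)[[1L]],
                  error = function(e) NULL)
  if (is.null(rec) || atomCount(rec) == 0L)
    stop("embedding failed for SMILES: ", smiles)
  n <- atomCount(rec)
  if (n > 1L) {
    zseed <- sum(utf8ToInt(smiles)) + 7L
    lift <- withLocalSeed(zseed, function()
      cbind(stats::rnorm(n, sd = 0.05), stats::rnorm(n, sd = 0.05),
            stats::rnorm(n, sd = 0.4)))
    coords(rec) <- coords(rec) * 1.4 + lift  # scale toward bond lengths
    if (minimize) {
      ff <- ffSetup(rec)
      coords(rec) <- ffMinimize(ff, coords(rec), maxit = 4000)$coords
      # settle on the global rotamer so unperturbed fixtures are
      # strain-free reference geometries
      gs <- globalMinimumSearch(rec, coords(rec), ff = ff)
      coords(rec) <- gs$globalMin@coords
    }
  }
  rec@fields <- list()
  fixtureCache[[key]] <- rec
  sdTitle(rec) <- title
  rec
}

#' Generate a deterministic SD fixture file
#'
#' Writes `nRecords` records cycling through the molecule pool, each
#' with `ID`, `SMILES` and `MW` data fields, and returns a manifest
#' of expected per-record values. The same seed yields byte-identical
#' files.
#'
#' @param path output SD file path.
#' @param nRecords number of records.
#' @param seed integer seed (records get deterministic titles derived
#'   from it).
#' @param pool named SMILES vector (default [fixtureSmilesPool()]).
#' @return Invisibly, a manifest data.frame with columns `title`,
#'   `name`, `smiles`, `mw`.
#' @export
makeSDFixture <- function(path, nRecords = 10L, seed = 1L,
                          pool = fixtureSmilesPool()) {
  idx <- if (nRecords > 0L)
    rep(seq_along(pool), length.out = nRecords) else integer()
  recs <- vector("list", nRecords)
  manifest <- data.frame(title = character(nRecords),
                         name = character(nRecords),
                         smiles = character(nRecords),
                         mw = numeric(nRecords),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nRecords)) {
    nm <- names(pool)[idx[i]]
    title <- sprintf("MOL_%d_%04d", as.integer(seed), i)
    rec <- embedSmiles(pool[[idx[i]]], title = title)
    mw <- molWeight(rec)
    sdField(rec, "ID") <- title
    sdField(rec, "SMILES") <- pool[[idx[i]]]
    sdField(rec, "MW") <- sprintf("%.2f", mw)
    recs[[i]] <- rec
    manifest$title[i] <- title
    manifest$name[i] <- nm
    manifest$smiles[i] <- pool[[idx[i]]]
    manifest$mw[i] <- mw
  }
  writeSD(recs, path)
  invisible(manifest)
}

#' Generate a strained 3D pose
#'
#' Embeds the molecule, minimizes it with the package force field,
#' then adds zero-mean Gaussian noise of scale `sigma` to every
#' coordinate, yielding a pose with known-positive single-point
#' strain. The same seed gives identical coordinates.
#'
#' @param smiles SMILES string (must be embeddable).
#' @param seed integer seed for the coordinate noise.
#' @param sigma noise scale in Angstrom.
#' @param title record title.
#' @return An [SDRecord-class] with perturbed 3D coordinates.
#' @export
makeStrainedPose <- function(smiles, seed = 1L, sigma = 0.15,
                             title = paste0("pose_", seed)) {
  rec <- embedSmiles(smiles, title = title)
  if (sigma > 0) {
    n <- atomCount(rec)
    noise <- withLocalSeed(seed, function()
      matrix(stats::rnorm(n * 3L, sd = sigma), n, 3L))
    coords(rec) <- coords(rec) + noise
  }
  rec
}
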