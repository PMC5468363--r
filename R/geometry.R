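# Geometry: torsions, superposition, symmetry-corrected RMSD.

#' Measure a proper torsion angle
#'
#' @param coords n x 3 coordinate matrix.
#' @param i,j,k,l atom indices defining the dihedral about bond j-k.
#' @return Angle in degrees in (-180, 180].
#' @export
getTorsion <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- crossProd(b1, b2)
  n2 <- crossProd(b2, b3)
  m <- crossProd(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

crossProd <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

# Atoms on the k-side of bond j-k (the direct j-k edge removed).
# Returns NULL if j is still reachable from k, i.e. the bond is in a
# ring and the two sides are not separable.
bondSide <- function(rec, j, k) {
  adj <- adjacency(rec)
  seen <- logical(atomCount(rec))
  queue <- k
  seen[k] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (v == k && w == j) next  # the cut bond itself
      if (w == j) return(NULL)    # reached j another way: ring bond
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

#' Set a torsion angle by rotating one side of a bond
#'
#' Rotates the atoms on the `l` side of bond `j`-`k` about the bond
#' axis so that the dihedral `i`-`j`-`k`-`l` takes the requested
#' value. Fails for ring bonds (the two sides are not separable).
#'
#' @param rec an [SDRecord-class] (supplies connectivity).
#' @param coords n x 3 coordinate matrix to modify.
#' @param i,j,k,l atom indices of the dihedral.
#' @param angle target angle, degrees.
#' @return The modified coordinate matrix.
#' @export
setTorsion <- function(rec, coords, i, j, k, l, angle) {
  current <- getTorsion(coords, i, j, k, l)
  delta <- (angle - current) * pi / 180
  side <- bondSide(rec, j, k)
  if (is.null(side))
    stop(sprintf("bond %d-%d is in a ring; torsion cannot be set", j, k))
  axis <- coords[k, ] - coords[j, ]
  axis <- axis / sqrt(sum(axis^2))
  rot <- rotationMatrix(axis, delta)
  pivot <- coords[k, ]
  coords[side, ] <- sweep(sweep(coords[side, , drop = FALSE], 2L, pivot) %*%
                            t(rot), 2L, pivot, `+`)
  coords
}

rotationMatrix <- function(axis, theta) {
  c0 <- cos(theta); s0 <- sin(theta); C <- 1 - c0
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(c0 + x * x * C, x * y * C - z * s0, x * z * C + y * s0,
           y * x * C + z * s0, c0 + y * y * C, y * z * C - x * s0,
           z * x * C - y * s0, z * y * C + x * s0, c0 + z * z * C),
         3L, 3L, byrow = TRUE)
}

plainRMSD <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Kabsch superposition of probe onto ref using the given row subsets;
# returns the transform applied to ALL probe rows and the fit RMSD on
# the subset.
kabsch <- function(probe, ref, probeSub, refSub) {
  pa <- probe[probeSub, , drop = FALSE]
  ra <- ref[refSub, , drop = FALSE]
  cp <- colMeans(pa); cr <- colMeans(ra)
  H <- t(sweep(pa, 2L, cp)) %*% sweep(ra, 2L, cr)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(sweep(probe, 2L, cp) %*% t(R), 2L, cr, `+`)
  list(coords = moved,
       rmsd = plainRMSD(moved[probeSub, , drop = FALSE], ra))
}

# heavy-atom automorphisms of the molecular graph, as a list of
# permutations of the heavy-atom indices (identity first). Colored by
# element and attached-hydrogen count. Returns identity only (with a
# warning) beyond the cap.
heavyAutomorphisms <- function(rec, cap = 10000L) {
  at <- atomTable(rec)
  heavy <- which(at$elem != "H")
  nh <- length(heavy)
  if (nh == 0L) return(list())
  map <- match(seq_len(nrow(at)), heavy)
  b <- bondTable(rec)
  hb <- b[at$elem[b$a1] != "H" & at$elem[b$a2] != "H", , drop = FALSE]
  adj <- adjacency(rec)
  hcount <- vapply(heavy, function(i) sum(at$elem[adj[[i]]] == "H"), 0L)
  color <- as.integer(factor(paste(at$elem[heavy], hcount)))
  if (nrow(hb) == 0L) {
    # no heavy-heavy bonds: permutations within identical colors; just identity
    return(list(seq_len(nh)))
  }
  g <- igraph::graph_from_edgelist(cbind(map[hb$a1], map[hb$a2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nh - igraph::vcount(g)))
  cnt <- tryCatch(igraph::count_isomorphisms(g, g,
            vertex.color1 = color, vertex.color2 = color),
          error = function(e) NA)
  if (is.na(cnt) || cnt > cap) {
    warning("automorphism count exceeds cap; symmetry correction skipped")
    return(list(seq_len(nh)))
  }
  maps <- igraph::graph.get.isomorphisms.vf2(g, g, vertex.color1 = color,
                                             vertex.color2 = color)
  lapply(maps, as.integer)
}

#' Align a conformer to a reference by minimizing heavy-atom RMSD
#'
#' Rigid-body (Kabsch) superposition on heavy atoms. With
#' `symmetry = TRUE` the graph automorphisms of the heavy-atom
#' skeleton (element- and H-count-colored, capped at 10000) are
#' enumerated and the atom mapping with the smallest fitted RMSD is
#' used, so topologically equivalent atoms (e.g. a flipped phenyl
#' ring) do not inflate the RMSD.
#'
#' @param rec an [SDRecord-class] providing elements and connectivity.
#' @param probe coordinates to align: a matrix or a
#'   [Conformer-class].
#' @param reference reference coordinates: a matrix or a
#'   [Conformer-class].
#' @param symmetry enumerate automorphisms (default `TRUE`).
#' @return A list with `coords` (all atoms of `probe`, transformed),
#'   `rmsd` (heavy-atom RMSD after superposition), and, when `probe`
#'   is a [Conformer-class], `conformer` (the aligned conformer with
#'   `rmsdToInput` set to the fitted RMSD).
#' @export
alignConformer <- function(rec, probe, reference, symmetry = TRUE) {
  pc <- if (is(probe, "Conformer")) probe@coords else probe
  rc <- if (is(reference, "Conformer")) reference@coords else reference
  if (nrow(pc) != nrow(rc))
    stop("probe and reference atom counts differ")
  if (nrow(pc) != atomCount(rec))
    stop("coordinates do not match the molecule")
  heavy <- which(atomTable(rec)$elem != "H")
  if (length(heavy) == 0L) heavy <- seq_len(nrow(pc))
  perms <- if (symmetry) heavyAutomorphisms(rec) else
    list(seq_along(heavy))
  best <- NULL
  for (p in perms) {
    fit <- kabsch(pc, rc, heavy[p], heavy)
    if (is.null(best) || fit$rmsd < best$rmsd) best <- fit
  }
  out <- list(coords = best$coords, rmsd = best$rmsd)
  if (is(probe, "Conformer")) {
    probe@coords <- best$coords
    probe@rmsdToInput <- best$rmsd
    out$conformer <- probe
  }
  out
}
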