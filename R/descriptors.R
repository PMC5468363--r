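# Element data, implicit hydrogens, and 2D descriptors.

# standard atomic weights (abridged, common organic/drug elements)
ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.085,
                 P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
                 Ca = 40.078, Br = 79.904, I = 126.904)

DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                     P = 3, S = 2, Cl = 1, Br = 1, I = 1)

adjacency <- function(rec) {
  n <- atomCount(rec)
  adj <- vector("list", n)
  b <- bondTable(rec)
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], b$a2[i])
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], b$a1[i])
  }
  adj
}

# bond-count graph distances from one atom (BFS)
graphDistances <- function(adj, from) {
  n <- length(adj)
  d <- rep.int(NA_integer_, n)
  d[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) if (is.na(d[w])) {
      d[w] <- d[v] + 1L
      queue <- c(queue, w)
    }
  }
  d
}

# per-atom sum of bond orders, aromatic (4) counted as 1.5
bondOrderSums <- function(rec) {
  n <- atomCount(rec)
  s <- numeric(n)
  b <- bondTable(rec)
  for (i in seq_len(nrow(b))) {
    o <- if (b$order[i] == 4L) 1.5 else as.numeric(b$order[i])
    s[b$a1[i]] <- s[b$a1[i]] + o
    s[b$a2[i]] <- s[b$a2[i]] + o
  }
  s
}

#' Implicit hydrogen counts
#'
#' Standard-valence model: implicit H = default valence (adjusted for
#' formal charge) minus the sum of explicit bond orders, floored at
#' zero. Aromatic bonds count 1.5. Elements without a default valence
#' contribute no implicit hydrogens.
#'
#' @param rec an [SDRecord-class].
#' @return Integer vector, one count per atom.
#' @export
implicitHCounts <- function(rec) {
  at <- atomTable(rec)
  n <- nrow(at)
  if (n == 0L) return(integer())
  bos <- bondOrderSums(rec)
  out <- integer(n)
  for (i in seq_len(n)) {
    v <- DEFAULT_VALENCE[at$elem[i]]
    if (is.na(v)) next
    ch <- at$charge[i]
    # charge adjustment for common organic cases (N+, O-, etc.)
    if (at$elem[i] %in% c("N", "P")) v <- v + ch
    if (at$elem[i] %in% c("O", "S")) v <- v + ch
    if (at$elem[i] == "C") v <- v - abs(ch)
    out[i] <- max(0L, as.integer(round(v - bos[i])))
  }
  out
}

#' Molecular weight
#'
#' Sum of standard atomic weights over all atoms, counting implicit
#' hydrogens.
#'
#' @param rec an [SDRecord-class].
#' @return Molecular weight in g/mol.
#' @export
molWeight <- function(rec) {
  at <- atomTable(rec)
  if (nrow(at) == 0L) return(0)
  m <- ATOMIC_MASS[at$elem]
  if (anyNA(m))
    stop("unknown element(s): ",
         paste(unique(at$elem[is.na(m)]), collapse = ", "))
  sum(m) + sum(implicitHCounts(rec)) * ATOMIC_MASS[["H"]]
}

#' Hydrogen-bond acceptor count (N + O)
#'
#' @param rec an [SDRecord-class].
#' @return Number of nitrogen plus oxygen atoms.
#' @export
countHBA <- function(rec) sum(atomTable(rec)$elem %in% c("N", "O"))

#' Hydrogen-bond donor count (NH + OH)
#'
#' Counts hydrogens (explicit or implicit) attached to nitrogen or
#' oxygen.
#'
#' @param rec an [SDRecord-class].
#' @return Number of N-H and O-H hydrogens.
#' @export
countHBD <- function(rec) {
  at <- atomTable(rec)
  if (nrow(at) == 0L) return(0L)
  no <- which(at$elem %in% c("N", "O"))
  if (length(no) == 0L) return(0L)
  adj <- adjacency(rec)
  explicitH <- vapply(no, function(i) sum(at$elem[adj[[i]]] == "H"), 0L)
  sum(explicitH) + sum(implicitHCounts(rec)[no])
}

# TRUE per bond if it lies in a ring (removing it keeps ends connected)
ringBonds <- function(rec) {
  b <- bondTable(rec)
  n <- atomCount(rec)
  out <- logical(nrow(b))
  if (nrow(b) == 0L) return(out)
  for (i in seq_len(nrow(b))) {
    adj <- vector("list", n)
    for (j in seq_len(nrow(b))[-i]) {
      adj[[b$a1[j]]] <- c(adj[[b$a1[j]]], b$a2[j])
      adj[[b$a2[j]]] <- c(adj[[b$a2[j]]], b$a1[j])
    }
    d <- graphDistances(adj, b$a1[i])
    out[i] <- !is.na(d[b$a2[i]])
  }
  out
}

#' Rotatable bond count
#'
#' Single, acyclic bonds between two non-terminal heavy atoms (each
#' end bonded to at least one other heavy atom). Amide C-N bonds are
#' not excluded.
#'
#' @param rec an [SDRecord-class].
#' @return Integer count.
#' @export
countRotatableBonds <- function(rec) nrow(rotatableBonds(rec))

# bond table subset of rotatable bonds
rotatableBonds <- function(rec) {
  b <- bondTable(rec)
  at <- atomTable(rec)
  if (nrow(b) == 0L) return(b[0L, ])
  adj <- adjacency(rec)
  heavyDeg <- vapply(seq_len(nrow(at)), function(i)
    sum(at$elem[adj[[i]]] != "H"), 0L)
  inRing <- ringBonds(rec)
  keep <- b$order == 1L & !inRing &
    at$elem[b$a1] != "H" & at$elem[b$a2] != "H" &
    heavyDeg[b$a1] >= 2L & heavyDeg[b$a2] >= 2L
  b[keep, , drop = FALSE]
}

# Convert a record to a ChemmineR SDFset (one compound). Returns NULL
# for empty/unconvertible molecules (ChemmineR requires at least one
# bond).
recordToSDFset <- function(rec) {
  if (atomCount(rec) == 0L || bondCount(rec) == 0L) return(NULL)
  lines <- c(formatMolblock(rec, 1L), "$$$$")
  tryCatch({
    cls <- methods::getClassDef("SDFstr", package = "ChemmineR")
    sdfstr <- methods::new(cls, a = list(lines))
    methods::as(sdfstr, "SDFset")
  }, error = function(e) NULL)
}

#' Lipophilicity estimate (cLogP class)
#'
#' Atom-contribution octanol/water partition estimate computed with
#' the OpenBabel descriptor engine (via ChemmineR/ChemmineOB).
#'
#' @param rec an [SDRecord-class] with at least one atom.
#' @return Numeric logP estimate.
#' @export
calcLogP <- function(rec) {
  sdf <- recordToSDFset(rec)
  if (is.null(sdf)) stop("cannot compute logP for an empty molecule")
  as.numeric(ChemmineR::propOB(sdf)[1L, "logP"])
}
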