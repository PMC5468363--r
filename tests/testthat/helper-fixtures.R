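# Shared fixture builders. Everything is generated in code; embedded
# pool molecules are cached per session by embedSmiles().

# a minimal hand-built record (no chemistry toolkit involved)
toyRecord <- function(title = "toy", fields = list()) {
  sdRecord(title = title,
           atoms = data.frame(elem = c("C", "H", "H", "H", "H"),
                              x = c(0, 1.09, -0.36, -0.36, -0.36),
                              y = c(0, 0, 1.03, -0.51, -0.51),
                              z = c(0, 0, 0, 0.89, -0.89),
                              charge = 0L),
           bonds = data.frame(a1 = 1L, a2 = 2:5, order = 1L),
           fields = fields)
}

# n simple distinct data-carrying records
toyRecords <- function(n, prefix = "R") {
  lapply(seq_len(n), function(i)
    toyRecord(title = paste0(prefix, i),
              fields = list(ID = paste0(prefix, i), IDX = as.character(i))))
}

# a stream that fails if pulled more than `limit` times
countingStream <- function(records, env) {
  i <- 0L
  env$pulled <- 0L
  newStream(function() {
    if (i >= length(records)) return(NULL)
    i <<- i + 1L
    env$pulled <- i
    records[[i]]
  })
}

# an endless stream of toy records
infiniteStream <- function() {
  i <- 0L
  newStream(function() {
    i <<- i + 1L
    toyRecord(title = paste0("inf", i), fields = list(IDX = as.character(i)))
  })
}

# registry fixture mirroring the rule-of-five dependency hierarchy:
# RO5 requires MW, cLogP, N_O, NH_OH; MW/N_O/NH_OH share one
# aggregate id (single merged invocation)
ro5Registry <- function(keepRequired = FALSE) {
  calcRegistry(list(
    calculatorSpec("MW", aggregateId = "PhysChem"),
    calculatorSpec("N_O", aggregateId = "PhysChem"),
    calculatorSpec("NH_OH", aggregateId = "PhysChem"),
    calculatorSpec("cLogP"),
    calculatorSpec("RO5",
                   requiredCalculators = c("MW", "cLogP", "N_O", "NH_OH"),
                   keepRequired = keepRequired)))
}

# random DAG registry on <= maxNodes nodes; edges only from later to
# earlier declarations so the graph is acyclic by construction.
# Aggregate ids are assigned at random to a subset of nodes.
randomRegistry <- function(maxNodes = 8L) {
  n <- sample(2:maxNodes, 1L)
  nms <- paste0("P", seq_len(n))
  aggPool <- c(NA, NA, "agg1", "agg2")
  specs <- lapply(seq_len(n), function(i) {
    deps <- if (i > 1L) nms[which(stats::runif(i - 1L) < 0.35)] else
      character()
    calculatorSpec(nms[i], requiredCalculators = deps,
                   keepRequired = stats::runif(1) < 0.3,
                   aggregateId = sample(aggPool, 1L))
  })
  calcRegistry(specs)
}

# exhaustive validity check of a plan against its registry: every
# dependency of every executed calculator is satisfied by an earlier
# (or same) step, and each needed calculator appears exactly once
planIsValid <- function(plan, registry, requested) {
  steps <- planSteps(plan)
  members <- lapply(steps, `[[`, "calculators")
  flat <- unlist(members)
  if (anyDuplicated(flat)) return(FALSE)
  stepOf <- stats::setNames(rep(seq_along(steps), lengths(members)), flat)
  # needed set: requested + transitive deps
  needed <- character()
  grow <- function(p) {
    if (p %in% needed) return(invisible())
    needed <<- c(needed, p)
    for (d in registry@specs[[p]]@requiredCalculators) grow(d)
  }
  for (r in requested) grow(r)
  if (!setequal(flat, needed)) return(FALSE)
  for (p in flat)
    for (d in registry@specs[[p]]@requiredCalculators)
      if (stepOf[[d]] >= stepOf[[p]]) return(FALSE)
  TRUE
}

# brute-force O(n^2) weak-domination Pareto filter (oracle)
bruteParetoKeep <- function(candidates, retained) {
  pts <- function(l) cbind(vapply(l, confRMSD, 0), vapply(l, confEnergy, 0))
  cp <- pts(candidates)
  allp <- rbind(cp, if (length(retained)) pts(retained))
  isRet <- c(rep(FALSE, nrow(cp)), rep(TRUE, nrow(allp) - nrow(cp)))
  keep <- logical(nrow(cp))
  for (i in seq_len(nrow(cp))) {
    dominated <- FALSE
    for (j in seq_len(nrow(allp))) {
      if (j == i) next
      le <- allp[j, 1] <= cp[i, 1] && allp[j, 2] <= cp[i, 2]
      lt <- allp[j, 1] < cp[i, 1] || allp[j, 2] < cp[i, 2]
      dup <- allp[j, 1] == cp[i, 1] && allp[j, 2] == cp[i, 2]
      # strict domination; exact duplicates: retained always wins,
      # among candidates the earlier index wins
      if (le && lt) { dominated <- TRUE; break }
      if (dup && (isRet[j] || j < i)) { dominated <- TRUE; break }
    }
    keep[i] <- !dominated
  }
  keep
}

fakeConformer <- function(rmsd, energy) {
  new("Conformer", coords = matrix(0, 1, 3), energy = energy,
      rmsdToInput = rmsd, role = "ensemble")
}
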