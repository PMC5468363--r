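# Calculator registry, dependency resolution, plan execution.

test_that("XML registries load, validate, and reject bad references", {
  reg <- defaultRegistry()
  expect_s4_class(reg, "CalcRegistry")
  expect_identical(names(reg@specs)[1:3], c("MW", "N_O", "NH_OH"))
  expect_identical(reg@specs$RO5@requiredCalculators,
                   c("MW", "cLogP", "N_O", "NH_OH"))
  expect_identical(reg@specs$MW@aggregateId, reg@specs$N_O@aggregateId)

  expect_error(loadRegistry(
    '<properties><property name="A"/><property name="A"/></properties>'),
    "duplicate")
  expect_error(loadRegistry(paste0(
    '<properties><property name="RO5">',
    "<requiredCalculators>cLogD</requiredCalculators>",
    "</property></properties>")),
    "RO5.*cLogD")
})

test_that("single-property and rule-of-five plans resolve correctly", {
  reg <- ro5Registry()
  p1 <- resolvePlan("MW", reg)
  expect_length(planSteps(p1), 1L)
  expect_identical(planSteps(p1)[[1L]]$calculators, "MW")

  # the shared-aggregate trio merges into one invocation; dependencies
  # all precede the dependent property
  p2 <- resolvePlan("RO5", reg)
  expect_length(planSteps(p2), 3L)
  members <- lapply(planSteps(p2), `[[`, "calculators")
  expect_identical(members[[1L]], c("MW", "N_O", "NH_OH"))
  expect_identical(members[[2L]], "cLogP")
  expect_identical(members[[3L]], "RO5")
  expect_true(planIsValid(p2, reg, "RO5"))
  expect_setequal(transientFields(p2), c("MW", "N_O", "NH_OH", "cLogP"))

  # requesting a dependency alongside keeps it (no double computation,
  # no stripping)
  p3 <- resolvePlan(c("RO5", "MW"), reg)
  expect_length(planSteps(p3), 3L)
  expect_false("MW" %in% transientFields(p3))
  expect_true(planIsValid(p3, reg, c("RO5", "MW")))
})

test_that("every ordering constraint holds on a diamond dependency graph", {
  reg <- calcRegistry(list(
    calculatorSpec("D"),
    calculatorSpec("B", requiredCalculators = "D"),
    calculatorSpec("C", requiredCalculators = "D"),
    calculatorSpec("A", requiredCalculators = c("B", "C"))))
  plan <- resolvePlan("A", reg)
  flat <- unlist(lapply(planSteps(plan), `[[`, "calculators"))
  expect_identical(sum(flat == "D"), 1L)
  expect_lt(which(flat == "D"), min(which(flat %in% c("B", "C"))))
  expect_true(planIsValid(plan, reg, "A"))
  # the returned order is among the valid permutations; any ordering
  # violating an edge is rejected by the oracle
  perms <- list(c("D", "B", "C", "A"), c("B", "D", "C", "A"),
                c("A", "B", "C", "D"))
  valid <- vapply(perms, function(p) {
    pos <- stats::setNames(seq_along(p), p)
    pos[["D"]] < pos[["B"]] && pos[["D"]] < pos[["C"]] &&
      pos[["B"]] < pos[["A"]] && pos[["C"]] < pos[["A"]]
  }, TRUE)
  expect_identical(valid, c(TRUE, FALSE, FALSE))
})

test_that("resolution is deterministic and valid over random DAG registries", {
  set.seed(101)
  for (trial in 1:60) {
    reg <- randomRegistry()
    nms <- names(reg@specs)
    requested <- sample(nms, sample.int(length(nms), 1L))
    plan <- tryCatch(resolvePlan(requested, reg), error = function(e) e)
    if (inherits(plan, "error")) {
      # only legitimate failure: aggregate merging created a cycle
      expect_match(conditionMessage(plan), "cycle")
      next
    }
    expect_true(planIsValid(plan, reg, requested),
                label = sprintf("trial %d plan validity", trial))
    plan2 <- resolvePlan(requested, reg)
    expect_identical(lapply(planSteps(plan), `[[`, "calculators"),
                     lapply(planSteps(plan2), `[[`, "calculators"))
  }
})

test_that("dependency cycles and unknown requests are reported", {
  reg <- calcRegistry(list(
    calculatorSpec("A", requiredCalculators = "B"),
    calculatorSpec("B", requiredCalculators = "A")))
  expect_error(resolvePlan("A", reg), "cycle.*A.*B|cycle.*B.*A")
  expect_error(resolvePlan("Z", ro5Registry()), "unknown")
})

test_that("builtin execution writes fields and strips transients", {
  plan <- resolvePlan("RO5", defaultRegistry())
  rec <- embedSmiles("CC(=O)Oc1ccccc1C(=O)O", "aspirin")
  out <- streamCollect(applyPlan(plan, list(rec)))[[1L]]
  # aspirin violates no rule-of-five criterion (independent values:
  # MW 180.16, cLogP ~1.3, donors 1, acceptors 4)
  expect_identical(sdField(out, "RO5"), "0")
  expect_false(any(c("MW", "cLogP", "N_O", "NH_OH") %in%
                     names(sdFields(out))))

  # requesting MW too keeps that field
  plan2 <- resolvePlan(c("RO5", "MW"), defaultRegistry())
  out2 <- streamCollect(applyPlan(plan2, list(rec)))[[1L]]
  expect_identical(sdField(out2, "MW"), "180.16")
  expect_false("cLogP" %in% names(sdFields(out2)))

  # zero records in, zero out
  expect_length(streamCollect(applyPlan(plan, list())), 0L)
})

test_that("builtin values agree with independent descriptor computations", {
  # methane MW from an atomic-mass table: 12.011 + 4 * 1.008 = 16.043
  methane <- toyRecord("methane")
  expect_equal(molWeight(methane), 16.043, tolerance = 0.01 / 16)
  plan <- resolvePlan("MW", defaultRegistry())
  out <- streamCollect(applyPlan(plan, list(methane)))[[1L]]
  expect_identical(sdField(out, "MW"), "16.04")

  # aspirin counts, verified by inspection of the structure:
  # 4 oxygens + 0 nitrogens = 4 acceptors, one carboxylic OH donor
  asp <- embedSmiles("CC(=O)Oc1ccccc1C(=O)O", "aspirin")
  expect_identical(countHBA(asp), 4L)
  expect_identical(countHBD(asp), 1L)
  expect_identical(countRotatableBonds(asp), 3L)
})

test_that("rendered scripts pipe steps in plan order and strip transients", {
  plan <- resolvePlan("RO5", defaultRegistry())
  txt <- renderScript(plan)
  parts <- strsplit(txt, " \\\n | ", fixed = TRUE)[[1L]]
  expect_length(parts, 4L)  # 3 calculator steps + strip stage
  expect_match(parts[1L], "calcstep .*-calcs MW,N_O,NH_OH")
  expect_match(parts[4L], "rmfields")

  soloPlan <- resolvePlan("MW", defaultRegistry())
  soloTxt <- renderScript(soloPlan)
  expect_false(grepl("rmfields", soloTxt))
  expect_false(grepl("\n", soloTxt, fixed = TRUE) &&
                 length(strsplit(soloTxt, " | ", fixed = TRUE)[[1L]]) > 1L)
})
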