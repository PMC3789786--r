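test_that("FBA solves the linear chain at the uptake cap", {
    m <- exampleChainModel(cap = 10)
    sol <- solveFBA(m)
    expect_equal(solutionStatus(sol), "optimal")
    expect_equal(objectiveValue(sol), 10)
    expect_true(checkSolution(m, sol))
    ## all exchange bounds zero -> objective 0, still optimal
    m0 <- setBounds(m, "EX_a", lb = 0, ub = 0)
    sol0 <- solveFBA(m0)
    expect_equal(solutionStatus(sol0), "optimal")
    expect_equal(objectiveValue(sol0), 0)
    ## a demanded flux beyond supply is infeasible, reported as such
    mi <- setBounds(m, "BIO", lb = 50)
    expect_equal(solutionStatus(solveFBA(mi)), "infeasible")
})

test_that("the respiratory chain yields exactly 2.5 ATP per NADH", {
    m <- electronChainModel(nadhBound = 1)
    sol <- solveFBA(m)
    expect_equal(solutionStatus(sol), "optimal")
    ## 10 protons exported per NADH (4 NDH + 4 bc1 + 2 oxidase share),
    ## 4 consumed per ATP by the two-sector ATPase
    expect_equal(objectiveValue(sol), 2.5, tolerance = 1e-9)
    expect_equal(objectiveValue(solveFBA(electronChainModel(4))), 10,
                 tolerance = 1e-9)
})

test_that("FBA objective matches the reference LP on small networks", {
    compared <- 0
    for (seed in 1:40) {
        m <- randomSmallModel(seed)
        a <- solveFBA(m, backend = "dense")
        b <- solveFBA(m, backend = "boot")
        ## the reference tableau code occasionally stalls numerically;
        ## such instances cannot arbitrate and are not counted
        if (solutionStatus(b) == "solver_failure") next
        compared <- compared + 1
        expect_equal(solutionStatus(a), solutionStatus(b), info = seed)
        if (solutionStatus(a) == "optimal")
            expect_equal(objectiveValue(a), objectiveValue(b),
                         tolerance = 1e-6, info = seed)
    }
    expect_gte(compared, 30)
})

test_that("FVA collapses to a point on a chain and spans parallel routes", {
    m <- exampleChainModel(cap = 10)
    sol <- solveFBA(m)
    fv <- fluxVariability(m, 1)
    expect_equal(fv$min, fv$max, tolerance = 1e-8)
    expect_equal(fv$max[match("BIO", fv$id)], 10, tolerance = 1e-8)
    ## two identical parallel paths carrying total v: each ranges [0, v]
    m2 <- twoPathModel(cap = 10)
    fv2 <- fluxVariability(m2, 1, c("P1", "P2"))
    expect_equal(fv2$min, c(0, 0), tolerance = 1e-8)
    expect_equal(fv2$max, c(10, 10), tolerance = 1e-8)
    ## a (0,0)-bounded reaction has range (0,0)
    m3 <- setBounds(m2, "P2", lb = 0, ub = 0)
    fv3 <- fluxVariability(m3, 1, "P2")
    expect_equal(c(fv3$min, fv3$max), c(0, 0))
})

test_that("FVA at full optimum brackets the FBA flux, per reaction", {
    m <- applyState(CORE$model, coreState("succinate", uptake_tier = 39.2))
    sol <- solveFBA(m)
    ids <- sample(reactionIds(m), 25)  # spot-check a reaction subset
    fv <- fluxVariability(m, 1, ids)
    v <- fluxes(sol)[ids]
    expect_true(all(v >= fv$min - 1e-6 & v <= fv$max + 1e-6))
})

test_that("relaxing a bound never decreases the optimum", {
    m <- applyState(CORE$model, coreState())
    base <- objectiveValue(solveFBA(m))
    for (rid in c("EX_aglc_e", "DMDA", "NARL")) {
        b <- bounds(m, rid)
        m2 <- setBounds(m, rid, lb = b$lb - 5, ub = b$ub + 5)
        expect_gte(objectiveValue(solveFBA(m2)), base - 1e-8)
    }
})

test_that("knockouts zero exactly the reactions their GPRs imply", {
    m <- CORE$model
    ## OR-redundant gene: no reaction changes
    mk <- applyKnockouts(m, "pgiB")
    expect_equal(reactions(mk)$lb, reactions(m)$lb)
    expect_equal(reactions(mk)$ub, reactions(m)$ub)
    ## the demethylase knockout closes exactly that reaction
    mk2 <- applyKnockouts(m, "dmdA")
    expect_equal(unlist(bounds(mk2, "DMDA")[, c("lb", "ub")]),
                 c(lb = 0, ub = 0))
    changed <- which(reactions(mk2)$ub != reactions(m)$ub |
                     reactions(mk2)$lb != reactions(m)$lb)
    expect_equal(reactionIds(m)[changed], "DMDA")
    ## plasmid loss equals per-reaction GPR evaluation
    plasmid <- genes(m)$id[genes(m)$replicon == "86 kb"]
    mk3 <- applyKnockouts(m, plasmid)
    expect_dead <- vapply(reactions(m)$gpr, function(g)
        nzchar(g) && !gprEvaluate(g, plasmid), logical(1), USE.NAMES = FALSE)
    expect_equal(reactions(mk3)$ub == 0 & reactions(mk3)$lb == 0,
                 expect_dead | (reactions(m)$ub == 0 & reactions(m)$lb == 0))
    ## unknown gene id errors
    expect_error(applyKnockouts(m, "not_a_gene"), "unknown gene")
})

test_that("knockout of a superset never grows faster than a subset", {
    m <- applyState(CORE$model, coreState("DMSP", illumination = 34.6))
    g1 <- objectiveValue(solveFBA(applyKnockouts(m, "dmdA")))
    g2 <- objectiveValue(solveFBA(applyKnockouts(m, c("dmdA", "sdaA"))))
    wt <- objectiveValue(solveFBA(m))
    expect_lte(g2, g1 + 1e-8)
    expect_lte(g1, wt + 1e-8)
})

test_that("blocked reactions are found on toys and on the core model", {
    ## a dead-end metabolite's only reaction is blocked
    mets <- data.frame(id = c("a_e", "a", "dead"),
                       compartment = c("e", "c", "c"),
                       stringsAsFactors = FALSE)
    rxns <- data.frame(id = c("EX_a", "T_a", "BIO", "TODEAD"),
                       lb = c(-10, 0, 0, 0), ub = c(0, 1000, 1000, 1000),
                       tags = c("exchange", "", "biomass", ""),
                       stringsAsFactors = FALSE)
    S <- matrix(0, 3, 4, dimnames = list(mets$id, rxns$id))
    S["a_e", "EX_a"] <- -1
    S["a_e", "T_a"] <- -1; S["a", "T_a"] <- 1
    S["a", "BIO"] <- -1
    S["a", "TODEAD"] <- -1; S["dead", "TODEAD"] <- 1
    m <- metabolicModel(mets, rxns, S, objective = "BIO")
    expect_equal(blockedReactions(m), "TODEAD")
    ## a feasible linear chain has no blocked reaction
    expect_length(blockedReactions(exampleChainModel()), 0)
    ## the planted dead end (and the constrained PFK) on the core model
    expect_setequal(blockedReactions(CORE$model), CORE$groundTruth$blocked)
})
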