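test_that("generation is deterministic for a given config", {
    a <- generateCoreModel(generatorConfig(seed = 7))
    b <- generateCoreModel(generatorConfig(seed = 7))
    expect_identical(reactions(a$model), reactions(b$model))
    expect_identical(metabolites(a$model), metabolites(b$model))
    expect_identical(a$groundTruth, b$groundTruth)
    ## hash-stable serialization: identical SBML bytes
    f1 <- tempfile(); f2 <- tempfile()
    writeSBML(a$model, f1); writeSBML(b$model, f2)
    expect_identical(readLines(f1), readLines(f2))
    ## another seed relocates the decoy paralogs
    c_ <- generateCoreModel(generatorConfig(seed = 99))
    expect_false(identical(a$groundTruth$orParalogs,
                           c_$groundTruth$orParalogs))
})

test_that("contradictory toggles are rejected", {
    expect_error(generatorConfig(dmspBranches = TRUE,
                                 dmspExchange = FALSE),
                 "contradictory")
})

test_that("every non-exempt reaction of the core model is mass balanced", {
    m <- CORE$model
    for (r in reactionIds(m)) {
        ok <- isBalanced(elementBalance(m, r))
        if (!is.na(ok)) expect_true(ok, info = r)
    }
    ## exempt reactions are only the boundary and biomass ones
    exempt <- vapply(reactionIds(m), function(r)
        elementBalance(m, r)$exempt, logical(1))
    expect_true(all(hasTag(m, reactionIds(m)[exempt], "exchange") |
                    hasTag(m, reactionIds(m)[exempt], "sink") |
                    hasTag(m, reactionIds(m)[exempt], "biomass")))
})

test_that("the core model grows where it should and not where it cannot", {
    expect_gt(growthAt(coreState("alpha-D-glucose")), 0)
    expect_gt(growthAt(coreState("succinate")), 0)
    ## all carbon exchanges closed: no growth even with light and both
    ## electron acceptors
    m <- applyState(CORE$model, coreState(illumination = 34.6,
                                          e_acceptors = "O2+NO3"))
    m <- setBounds(m, "EX_aglc_e", lb = 0, ub = 0)
    sol <- solveFBA(m)
    expect_equal(solutionStatus(sol), "optimal")
    expect_equal(objectiveValue(sol), 0, tolerance = 1e-9)
})

test_that("the phosphofructokinase is present but constrained to zero", {
    expect_equal(unlist(bounds(CORE$model, "PFK")[, c("lb", "ub")]),
                 c(lb = 0, ub = 0))
    on <- generateCoreModel(generatorConfig(pfkEnabled = TRUE))
    expect_equal(bounds(on$model, "PFK")$ub, 1000)
    ## the enabled-PFK model is not identical but shares the gene set
    expect_identical(genes(on$model), genes(CORE$model))
})

test_that("loss of the rhamnose plasmid is lethal in every state", {
    plasmid <- genes(CORE$model)$id[
        genes(CORE$model)$replicon == "86 kb"]
    mk <- applyKnockouts(CORE$model, plasmid)
    for (st in list(coreState(), coreState("succinate", uptake_tier = 39.2),
                    coreState("DMSP", illumination = 34.6),
                    coreState("succinate", e_acceptors = "DMSO",
                              uptake_tier = 39.2)))
        expect_lt(growthAt(st, mk), 1e-9)
})

test_that("genome composition fixture has exact GC and is reproducible", {
    g <- generateGenomeComposition(seed = 3, gcContent = 0.66)
    expect_equal((g$baseCounts[["G"]] + g$baseCounts[["C"]]) /
                 sum(g$baseCounts), 0.66, tolerance = 1e-9)
    expect_equal(g$baseCounts[["A"]], g$baseCounts[["T"]])
    g2 <- generateGenomeComposition(seed = 3, gcContent = 0.66)
    expect_identical(g, g2)
    expect_false(identical(
        g$codonUsage, generateGenomeComposition(seed = 4)$codonUsage))
})

test_that("uniform codon usage yields AA fractions at codon multiplicity", {
    codons <- names(RoseoFBA:::GENETIC_CODE_TABLE)
    uniform <- stats::setNames(rep(1, 64), codons)
    aa <- monomerFractionsFromGenome(c(A = 1, C = 1, G = 1, T = 1),
                                     uniform)$protein
    ## e.g. leucine has six codons, methionine one, of 61 coding codons
    expect_equal(aa[["L"]], 6 / 61)
    expect_equal(aa[["M"]], 1 / 61)
    expect_equal(aa[["W"]], 1 / 61)
})

test_that("ground truth writes as a JSON sidecar", {
    f <- tempfile(fileext = ".json")
    writeGroundTruth(CORE$groundTruth, f)
    gt <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_setequal(gt$blocked, CORE$groundTruth$blocked)
    expect_equal(gt$atpPerNadh, 2.5)
})

test_that("report writers emit readable tables", {
    d <- tempfile()
    m2 <- applyState(CORE$model, coreState(motile_fraction = 0))
    sol <- solveFBA(m2)
    f <- tempfile(fileext = ".tsv")
    writeFluxTSV(sol, f, fva = fluxVariability(m2, 1, c("CS", "PC")))
    tab <- utils::read.delim(f)
    expect_equal(nrow(tab), nReactions(m2))
    expect_true(all(c("flux", "min", "max") %in% names(tab)))
    fs <- tempfile(fileext = ".json")
    writeModelStats(CORE$model, fs)
    st <- jsonlite::read_json(fs)
    expect_equal(st$reactions, nReactions(CORE$model))
})
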