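test_that("demethylation contribution equals capacity over uptake", {
    st <- coreState("DMSP", illumination = 34.6)
    dc <- demethylationContribution(CORE$model, st)
    cap <- CORE$groundTruth$demethylation$cap
    expect_equal(dc$uptake, 2.4)            # 12 carbon atoms / 5 C
    expect_equal(dc$maxFraction, cap / 2.4, tolerance = 1e-6)
    expect_equal(dc$minFraction, dc$maxFraction, tolerance = 1e-6)
    expect_false(dc$zeroGrowth)
    ## fractions bracket the share implied by the single FBA solution
    m2 <- applyState(CORE$model, st)
    sol <- solveFBA(m2)
    f1 <- fluxes(sol)[["DMDA"]] / -fluxes(sol)[["EX_dmsp_e"]]
    expect_gte(f1, dc$minFraction - 1e-6)
    expect_lte(f1, dc$maxFraction + 1e-6)
})

test_that("branch knockouts drive the fraction to its extremes", {
    st <- coreState("DMSP", illumination = 34.6)
    ## demethylase knocked out: nothing demethylated
    m1 <- applyKnockouts(CORE$model, "dmdA")
    dc1 <- demethylationContribution(m1, st)
    expect_equal(dc1$maxFraction, 0, tolerance = 1e-8)
    ## both cleavage isozymes knocked out: everything demethylated
    m2 <- applyKnockouts(CORE$model, c("dddL", "dddD"))
    dc2 <- demethylationContribution(m2, st)
    expect_equal(dc2$minFraction, 1, tolerance = 1e-6)
    expect_equal(dc2$maxFraction, 1, tolerance = 1e-6)
    ## a non-DMSP state is refused
    expect_error(demethylationContribution(CORE$model, coreState()),
                 "must be DMSP")
})

test_that("the demethylation-capped fraction falls with the uptake tier", {
    f <- vapply(c(12, 39.2), function(tier) {
        demethylationContribution(
            CORE$model, coreState("DMSP", uptake_tier = tier,
                                  illumination = 34.6))$maxFraction
    }, 0)
    expect_true(all(diff(f) < 0))
})

test_that("DMS screen finds the demethylation knockout at f/(1-f)", {
    st <- as.data.frame(coreState("DMSP", illumination = 34.6),
                        stringsAsFactors = FALSE)
    scr <- dmsOverproductionScreen(CORE$model, st,
                                   c("dmdA", "sdaA", "xylA"))
    ## the unrelated gene is omitted: growth and DMS unchanged
    expect_false("xylA" %in% scr$gene)
    expect_setequal(scr$gene, c("dmdA", "sdaA"))
    ## stoichiometric redistribution: blocking a branch that carried a
    ## fraction f of the uptake raises DMS export by f/(1-f)
    f <- demethylationContribution(CORE$model,
                                   as.list(st[1, ]))$maxFraction
    expect_equal(scr$dmsGain, rep(100 * f / (1 - f), 2),
                 tolerance = 1e-6)
    expect_true(all(scr$relativeGrowth > 0 & scr$relativeGrowth < 100))
    ## volatile bookkeeping: wild-type DMS max plus the demethylated
    ## share equals total DMSP uptake (cleavage makes one DMS per DMSP)
    expect_equal(scr$wtDmsMax[1] + f * 2.4, 2.4, tolerance = 1e-6)
    ## the serine-lyase knockout strangles demethylation indirectly,
    ## mirroring the demethylase knockout
    expect_equal(scr$dmsGain[scr$gene == "sdaA"],
                 scr$dmsGain[scr$gene == "dmdA"], tolerance = 1e-6)
})

test_that("aerobic denitrification appears only in the light", {
    grid <- list(carbon_source = "ethanol", n_source = "ammonia",
                 e_acceptors = "O2+NO3", uptake_tier = 1,
                 illumination = c(34.6, 0), motile_fraction = 0)
    states <- enumerateStates(grid)
    hit <- aerobicDenitrificationStates(CORE$model, states)
    expect_equal(hit, c(TRUE, FALSE))
    ## O2-only states are rejected up front
    expect_error(aerobicDenitrificationStates(
        CORE$model, as.data.frame(coreState(),
                                  stringsAsFactors = FALSE)),
        "O2 and NO3")
})

test_that("dark energy-limited states never admit aerobic denitrification", {
    ## in darkness, respiring nitrate forfeits proton translocation, so
    ## wherever energy limits growth the optimal face excludes it; the
    ## one exception is carbon-limited darkness on a highly reduced
    ## substrate at high uptake (ethanol, tier 12), where surplus
    ## electrons must be disposed of regardless of the energy budget
    grid <- list(carbon_source = c("succinate", "DMSP"),
                 n_source = "ammonia", e_acceptors = "O2+NO3",
                 uptake_tier = c(1, 12), illumination = 0,
                 motile_fraction = c(0, 0.1))
    states <- enumerateStates(grid)
    states <- rbind(states,
                    as.data.frame(coreState("ethanol", "ammonia",
                                            "O2+NO3", 1, 0, 0),
                                  stringsAsFactors = FALSE))
    expect_false(any(aerobicDenitrificationStates(CORE$model, states)))
})

test_that("branch point reports split percentages that sum to 100", {
    m2 <- applyState(CORE$model, coreState(motile_fraction = 0))
    sol <- solveFBA(m2)
    rep_ <- branchPointReport(sol, m2, "oaa")
    expect_gt(rep_$total, 0)
    prod <- rep_$table[rep_$table$side == "producer", ]
    cons <- rep_$table[rep_$table$side == "consumer", ]
    expect_equal(sum(prod$percent), 100, tolerance = 0.1)
    expect_equal(sum(cons$percent), 100, tolerance = 0.1)
    ## percentages equal hand-computed shares of the flux vector
    S <- stoichiometricMatrix(m2)
    thru <- as.numeric(S["oaa", ]) * fluxes(sol)[reactionIds(m2)]
    expect_equal(rep_$total, sum(thru[thru > 1e-6]), tolerance = 1e-6)
    for (k in seq_len(nrow(prod)))
        expect_equal(prod$percent[k],
                     100 * thru[[prod$reaction[k]]] / rep_$total,
                     tolerance = 1e-6)
    ## single producer/consumer metabolite: both sides 100%
    rep2 <- branchPointReport(sol, m2, "glc")
    expect_equal(rep2$table$percent, c(100, 100), tolerance = 1e-6)
    ## unused metabolite: total 0, empty table
    rep3 <- branchPointReport(sol, m2, "orphB")
    expect_equal(rep3$total, 0)
    expect_equal(nrow(rep3$table), 0)
    expect_error(branchPointReport(sol, m2, "nope"), "unknown metabolite")
})

test_that("knockout phenotype classes recover the planted genes", {
    grid <- list(carbon_source = c("alpha-D-glucose", "succinate"),
                 n_source = "ammonia",
                 e_acceptors = c("O2", "DMSO", "NO3"),
                 uptake_tier = 12, illumination = c(34.6, 0),
                 motile_fraction = 0)
    states <- enumerateStates(grid)
    gts <- c(list(genotype("wildtype")),
             lapply(c("rmlA", "cbiD", "pgiB"), function(g)
                 genotype(g, disabledGenes = g)))
    camp <- runCampaign(CORE$model, states, gts)
    cls <- classifyKnockoutPhenotypes(camp)
    got <- stats::setNames(cls$classes$class, cls$classes$gene)
    expect_equal(got[["rmlA"]], "always_lethal")
    expect_equal(got[["pgiB"]], "no_effect")
    expect_equal(got[["cbiD"]], "multifaceted")
    ## the corrinoid-branch knockout is lethal exactly anaerobically
    anaerobic <- !grepl("O2", states$e_acceptors)
    wt_grows <- camp$records$growth[camp$records$genotype ==
                                    "wildtype"] > 1e-6
    lethal <- cls$matrix["cbiD", ] == "lethal"
    expect_equal(lethal, anaerobic & wt_grows)
    ## fractions cover every class and sum to 100
    expect_equal(sum(cls$fractions), 100)
    expect_error(classifyKnockoutPhenotypes(
        structure(list(records = camp$records[
            camp$records$genotype != "wildtype", ]),
            class = "CampaignResult")),
        "wildtype")
})
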