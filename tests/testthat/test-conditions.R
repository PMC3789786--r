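test_that("state enumeration spans the full cross-product", {
    states <- enumerateStates()
    expect_equal(nrow(states), 7020)  # 26 x 3 x 5 x 3 x 2 x 3
    expect_equal(nrow(unique(states)), 7020)
    ## deterministic lexicographic order: first parameter varies slowest
    expect_equal(states$carbon_source[1:54],
                 rep("(R)-3-hydroxybutanoate", 54))
    expect_equal(states$motile_fraction[1:3], c(0, 0.1, 0.2))
    ## degenerate grids
    one <- enumerateStates(list(a = 1, b = "x"))
    expect_equal(nrow(one), 1)
    four <- enumerateStates(list(carbon = c("g", "s"), light = c(0, 1)))
    expect_equal(nrow(four), 4)
    expect_error(enumerateStates(list(a = 1, b = character())),
                 "at least one value")
})

test_that("grid cardinality is the product of parameter cardinalities", {
    grid <- list(a = 1:4, b = letters[1:3], c = c(0.1, 0.2))
    expect_equal(nrow(enumerateStates(grid)), prod(lengths(grid)))
})

test_that("carbon uptake bounds are normalized per carbon atom", {
    expect_equal(carbonUptakeBound("alpha-D-glucose", 12), 2)
    expect_equal(carbonUptakeBound("succinate", 39.2), 9.8)
    expect_equal(carbonUptakeBound("pyruvate", 1), 1 / 3)
    expect_equal(carbonUptakeBound(4, 12), 3)  # numeric carbon count
    expect_error(carbonUptakeBound(0, 12), "at least 1")
    expect_error(carbonUptakeBound("unobtainium", 12), "unknown carbon")
})

test_that("motility flux is anchored at the published operating point", {
    expect_equal(motilityFlux(0), 0)
    expect_equal(motilityFlux(0.10), 24)
    expect_equal(motilityFlux(0.20), 48)  # linear in the motile fraction
    expect_error(motilityFlux(1.2), "\\[0, 1\\]")
    ## the closed-form motor estimate N v / m is three orders of
    ## magnitude below the anchor - both are exposed
    expect_equal(motilityFluxFromPhysics(0.10), 0.0239,
                 tolerance = 0.01)
})

test_that("applyState translates a state into bounds and objective", {
    m <- CORE$model
    ## dark aerobic: the bacteriochlorophyll biomass variant
    m1 <- applyState(m, coreState(illumination = 0, e_acceptors = "O2"))
    expect_equal(objectiveReaction(m1), "BIOMASS_BCHL")
    ## light anaerobic DMSO: bchl-free variant, photon uptake bound 34.6
    m2 <- applyState(m, coreState(e_acceptors = "DMSO",
                                  illumination = 34.6))
    expect_equal(objectiveReaction(m2), "BIOMASS")
    expect_equal(bounds(m2, "EX_photon_e")$lb, -34.6)
    expect_equal(bounds(m2, "EX_o2_e")$lb, 0)
    expect_equal(bounds(m2, "EX_dmso_e")$lb, -1000)
    ## zero-motility dark glucose tier 12: uptake 2, motility 0, photon 0
    m3 <- applyState(m, coreState(motile_fraction = 0))
    expect_equal(bounds(m3, "EX_aglc_e")$lb, -2)
    expect_equal(unlist(bounds(m3, "MOTILITY")[, c("lb", "ub")]),
                 c(lb = 0, ub = 0))
    expect_equal(bounds(m3, "EX_photon_e")$lb, 0)
    ## non-selected carbon sources are fully closed
    expect_equal(unlist(bounds(m3, "EX_succ_e")[, c("lb", "ub")]),
                 c(lb = 0, ub = 0))
    ## 10% motility pins the proton drain at 24
    m4 <- applyState(m, coreState())
    expect_equal(unlist(bounds(m4, "MOTILITY")[, c("lb", "ub")]),
                 c(lb = 24, ub = 24))
    ## the corrinoid oxygen supply stays open even anaerobically
    expect_equal(bounds(m2, "EX_o2rib_e")$lb, -1000)
    ## photon equality mode pins rather than caps the uptake
    m5 <- applyState(m, coreState(illumination = 34.6),
                     photonEquality = TRUE)
    expect_equal(unlist(bounds(m5, "EX_photon_e")[, c("lb", "ub")]),
                 c(lb = -34.6, ub = -34.6))
    ## a model lacking a required reaction gives a named error
    sub <- exampleChainModel()
    expect_error(applyState(sub, coreState()), "lacks required")
})

test_that("growth responds monotonically to tier, light and motility", {
    for (cs in c("alpha-D-glucose", "succinate")) {
        g_tier <- vapply(c(1, 12, 39.2), function(t)
            growthAt(coreState(cs, uptake_tier = t)), 0)
        expect_true(all(diff(g_tier) >= -1e-8))
        g_light <- growthAt(coreState(cs, illumination = 34.6))
        expect_gte(g_light, g_tier[2] - 1e-8)
        g_mot <- vapply(c(0, 0.1, 0.2), function(f)
            growthAt(coreState(cs, motile_fraction = f)), 0)
        expect_true(all(diff(g_mot) <= 1e-8))
    }
})

test_that("low-tier dark DMSP cannot cover maintenance plus motility", {
    expect_equal(growthAt(coreState("DMSP", uptake_tier = 1,
                                    illumination = 0,
                                    motile_fraction = 0.1)), 0)
    ## in the light the same state grows, on demethylation alone
    expect_gt(growthAt(coreState("DMSP", uptake_tier = 1,
                                 illumination = 34.6,
                                 motile_fraction = 0.1)), 0)
})

test_that("genotypes apply knockouts and reaction toggles", {
    expect_error(genotype("x", disabledReactions = "A",
                          enabledReactions = "A"),
                 "both disabled and enabled")
    m <- applyState(CORE$model, coreState())
    pfk <- genotype("pfk+", enabledReactions = "PFK")
    m2 <- applyGenotype(m, pfk)
    expect_equal(bounds(m2, "PFK")$ub, 1000)
    ## enabling the phosphofructokinase helps on glucose only
    expect_gt(objectiveValue(solveFBA(m2)), objectiveValue(solveFBA(m)))
    ms <- applyState(CORE$model, coreState("succinate"))
    expect_equal(objectiveValue(solveFBA(applyGenotype(ms, pfk))),
                 objectiveValue(solveFBA(ms)), tolerance = 1e-9)
})

test_that("a mini-campaign reproduces individually solved cells", {
    states <- enumerateStates(list(
        carbon_source = c("alpha-D-glucose", "succinate"),
        n_source = "ammonia", e_acceptors = "O2", uptake_tier = 12,
        illumination = c(0, 34.6), motile_fraction = 0.1))
    gts <- list(genotype("wildtype"), genotype("rmlA-", "rmlA"))
    camp <- runCampaign(CORE$model, states, gts)
    expect_equal(nrow(camp$records), 8)
    for (k in seq_len(nrow(camp$records))) {
        rec <- camp$records[k, ]
        m2 <- applyState(CORE$model, as.list(
            rec[, names(states)]))
        m2 <- applyGenotype(m2, gts[[match(rec$genotype,
                                           c("wildtype", "rmlA-"))]])
        sol <- solveFBA(m2)
        ref <- if (solutionStatus(sol) == "optimal")
            max(0, objectiveValue(sol)) else 0
        expect_equal(rec$growth, ref, tolerance = 1e-9)
    }
    ## the universally essential knockout never grows
    expect_true(all(camp$records$growth[camp$records$genotype == "rmlA-"]
                    < 1e-9))
})

test_that("identical flux distributions are grouped together", {
    ## states differing only in an unused nutrient share a distribution
    states <- enumerateStates(list(
        carbon_source = "alpha-D-glucose", n_source = "ammonia",
        e_acceptors = c("O2", "O2+NO3"), uptake_tier = 12,
        illumination = 0, motile_fraction = c(0.1, 0.2)))
    ## FVA-canonicalized grouping: alternate optima of one face must
    ## not split a group when only an unused nutrient differs
    camp <- groupFluxDistributions(runCampaign(CORE$model, states,
                                               fva = TRUE))
    grp <- camp$records$group
    ## dark: nitrate stays untouched, O2 vs O2+NO3 collapse pairwise
    expect_equal(grp[camp$records$e_acceptors == "O2"],
                 grp[camp$records$e_acceptors == "O2+NO3"])
    ## different motile fractions have different distributions
    expect_true(grp[1] != grp[2])
})

test_that("all-zero-growth records form a single group", {
    states <- enumerateStates(list(
        carbon_source = "DMSP", n_source = "ammonia",
        e_acceptors = c("O2", "NO3", "DMSO"), uptake_tier = 1,
        illumination = 0, motile_fraction = 0.2))
    camp <- groupFluxDistributions(runCampaign(CORE$model, states))
    expect_true(all(camp$records$growth == 0))
    expect_equal(length(unique(camp$records$group)), 1)
})

test_that("FVA canonicalization merges alternate optima of one face", {
    ## two parallel paths: raw vertices may differ, midpoints agree
    m <- twoPathModel()
    states <- data.frame(carbon_source = "A", stringsAsFactors = FALSE)
    camp <- structure(list(
        records = data.frame(genotype = c("a", "b"), growth = c(10, 10),
                             status = "optimal", group = NA_integer_),
        fluxes = rbind(c(-10, 10, 10, 0, 10), c(-10, 10, 0, 10, 10)),
        fvaMin = rbind(c(-10, 10, 0, 0, 10), c(-10, 10, 0, 0, 10)),
        fvaMax = rbind(c(-10, 10, 10, 10, 10), c(-10, 10, 10, 10, 10))),
        class = "CampaignResult")
    colnames(camp$fluxes) <- colnames(camp$fvaMin) <-
        colnames(camp$fvaMax) <- reactionIds(m)
    camp <- groupFluxDistributions(camp)
    expect_equal(camp$records$group, c(1, 1))
})

test_that("campaign and biomass configs round-trip through JSON", {
    f <- tempfile(fileext = ".json")
    jsonlite::write_json(list(
        grid = list(carbon_source = c("alpha-D-glucose"),
                    n_source = "ammonia", e_acceptors = "O2",
                    uptake_tier = c(1, 12), illumination = 0,
                    motile_fraction = 0),
        genotypes = list(list(label = "wildtype"),
                         list(label = "dmdA-",
                              disabledGenes = "dmdA"))), f,
        auto_unbox = TRUE)
    cfg <- readCampaignConfig(f)
    expect_equal(nrow(enumerateStates(cfg$grid)), 2)
    expect_equal(vapply(cfg$genotypes, `[[`, "", "label"),
                 c("wildtype", "dmdA-"))
    spec <- syntheticBiomassSpec()
    f2 <- tempfile(fileext = ".json")
    jsonlite::write_json(list(
        macroFractions = as.list(spec@macroFractions),
        monomerFractions = lapply(spec@monomerFractions, as.list),
        monomerMasses = as.list(spec@monomerMasses),
        gam = 53.95, ngam = 3.15), f2, auto_unbox = TRUE, digits = NA)
    spec2 <- readBiomassSpec(f2)
    expect_equal(spec2@macroFractions, spec@macroFractions)
    expect_equal(spec2@gam, 53.95)
})
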