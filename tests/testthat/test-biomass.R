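test_that("remainder fraction is one minus the listed fractions", {
    f <- c(protein = 0.4534, dna = 0.0322, rna = 0.0411, lipids = 0.1402,
           phb = 0.2470, bchl = 0.0008, lps = 0.0400,
           peptidoglycan = 0.0250, unknown = 0.0010)
    ## tabulated rows sum to 0.9807, the exact remainder is 0.0193 (a
    ## printed 1.91% carries 0.02% of rounding)
    expect_equal(remainderFraction(f), 0.0193, tolerance = 1e-12)
    expect_equal(remainderFraction(numeric(0)), 1)
    expect_equal(remainderFraction(c(x = 0.9)), 0.1)
    expect_error(remainderFraction(c(a = 0.7, b = 0.5)), "more than 1")
})

test_that("biomass spec validity catches bad compositions", {
    expect_s4_class(syntheticBiomassSpec(), "BiomassSpec")
    expect_error(biomassSpec(
        macroFractions = c(protein = 0.6, dna = 0.1, soluble = 0.1),
        monomerFractions = list(protein = c(ala = 1)),
        monomerMasses = c(ala = 0.089)), "sum")
    expect_error(biomassSpec(
        macroFractions = c(protein = 0.9, soluble = 0.1),
        monomerFractions = list(protein = c(ala = 0.7),
                                soluble = c(ala = 1)),
        monomerMasses = c(ala = 0.089)), "do not sum")
})

test_that("biomass coefficients reproduce the mass bookkeeping", {
    ## one macromolecule at 100% with a 0.1 g/mmol monomer: 10 mmol/gDW
    spec <- biomassSpec(macroFractions = c(protein = 1, bchl = 0),
                        monomerFractions = list(protein = c(mono = 1)),
                        monomerMasses = c(mono = 0.1))
    bio <- buildBiomassReactions(spec, c(mono = "m1"),
                                 energyIds = c(atp = "atp", h2o = "h2o",
                                               adp = "adp", pi = "pi",
                                               h = "h"),
                                 bchlId = "bchl")
    expect_equal(unname(bio$plain$stoich[["m1"]]), -10)
    ## GAM term present in both variants
    expect_equal(unname(bio$plain$stoich[["atp"]]), -53.95)
    expect_equal(unname(bio$bchl$stoich[["atp"]]), -53.95)
    expect_equal(bio$plain$massPerGDW, 1, tolerance = 1e-9)
})

test_that("the synthetic composition closes to one gram per gDW", {
    spec <- syntheticBiomassSpec()
    truth <- CORE$groundTruth
    expect_lt(abs(truth$biomassMassPerGDW[["plain"]] - 1), 0.01)
    ## protein monomers contribute their tabulated mass fraction
    coefs <- spec@macroFractions[["protein"]] /
        spec@monomerMasses[["ala"]]
    expect_equal(coefs * spec@monomerMasses[["ala"]], 0.4534)
})

test_that("the two variants differ only in the bacteriochlorophyll term", {
    S <- stoichiometricMatrix(CORE$model)
    d <- S[, "BIOMASS_BCHL"] - S[, "BIOMASS"]
    nz <- which(d != 0)
    expect_equal(rownames(S)[nz], "bchl")
    ## 4 nmol/mg protein x 453.4 mg protein/gDW = 1.8136e-3 mmol/gDW
    expect_equal(unname(d[nz]), -4e-6 * 453.4, tolerance = 1e-12)
})

test_that("doubling monomer masses halves every coefficient", {
    spec <- syntheticBiomassSpec()
    spec2 <- biomassSpec(macroFractions = spec@macroFractions,
                         monomerFractions = spec@monomerFractions,
                         monomerMasses = spec@monomerMasses * 2)
    cat_ <- stats::setNames(names(spec@monomerMasses),
                            names(spec@monomerMasses))
    eids <- c(atp = "atp", h2o = "h2o", adp = "adp", pi = "pi", h = "h")
    b1 <- buildBiomassReactions(spec, cat_, eids, "bchl")
    b2 <- buildBiomassReactions(spec2, cat_, eids, "bchl")
    mono <- setdiff(names(b1$plain$stoich), c("atp", "h2o", "adp", "pi", "h"))
    expect_equal(b2$plain$stoich[mono], b1$plain$stoich[mono] / 2)
})

test_that("a missing monomer metabolite is a named error", {
    spec <- biomassSpec(macroFractions = c(protein = 1, bchl = 0),
                        monomerFractions = list(protein = c(orphan = 1)),
                        monomerMasses = c(orphan = 0.1))
    expect_error(buildBiomassReactions(spec, c(other = "m"),
                                       energyIds = c(atp = "a", h2o = "w",
                                                     adp = "d", pi = "p",
                                                     h = "h"),
                                       bchlId = "b"),
                 "orphan")
})

test_that("genome-derived monomer fractions respect strand symmetry", {
    eq <- monomerFractionsFromGenome(c(A = 10, C = 10, G = 10, T = 10))
    expect_equal(unname(eq$dna), rep(0.25, 4))
    ## 60% GC: dG = dC = 0.30, dA = dT = 0.20 regardless of strand bias
    gc <- monomerFractionsFromGenome(c(A = 25, C = 35, G = 25, T = 15))
    expect_equal(gc$dna, c(dA = 0.2, dC = 0.3, dG = 0.3, dT = 0.2))
    expect_equal(sum(gc$rna), 1)
    expect_error(monomerFractionsFromGenome(c(A = 1, C = 1)), "baseCounts")
})

test_that("amino acid fractions follow a hand-translated codon tally", {
    ## 9-codon toy ORF: ATG GCT GCT AAA GCC TTT AAA GGT TAA
    codons <- c(ATG = 1, GCT = 2, AAA = 2, GCC = 1, TTT = 1, GGT = 1,
                TAA = 1)
    aa <- monomerFractionsFromGenome(c(A = 1, C = 1, G = 1, T = 1),
                                     codons)$protein
    ## stop ignored: 8 coding codons -> M1 A3 K2 F1 G1
    expect_equal(aa[["M"]], 1 / 8)
    expect_equal(aa[["A"]], 3 / 8)
    expect_equal(aa[["K"]], 2 / 8)
    expect_equal(sum(aa), 1)
})
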