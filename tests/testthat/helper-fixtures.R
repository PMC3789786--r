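## Shared fixtures: the seeded core model (built once per session), toy
## networks, random small LPs for oracle-equivalence checks, and a
## legacy Level-2 SBML fixture built in code.

CORE <- generateCoreModel()

coreState <- function(carbon_source = "alpha-D-glucose",
                      n_source = "ammonia", e_acceptors = "O2",
                      uptake_tier = 12, illumination = 0,
                      motile_fraction = 0.1) {
    list(carbon_source = carbon_source, n_source = n_source,
         e_acceptors = e_acceptors, uptake_tier = uptake_tier,
         illumination = illumination, motile_fraction = motile_fraction)
}

growthAt <- function(state, model = CORE$model, ...) {
    sol <- solveFBA(applyState(model, state, ...))
    if (solutionStatus(sol) == "optimal") objectiveValue(sol) else 0
}

## two parallel identical routes from A to the biomass drain
twoPathModel <- function(cap = 10) {
    mets <- data.frame(id = c("a_e", "a", "b"),
                       compartment = c("e", "c", "c"),
                       formula = "C1", stringsAsFactors = FALSE)
    rxns <- data.frame(id = c("EX_a", "T_a", "P1", "P2", "BIO"),
                       lb = c(-cap, 0, 0, 0, 0), ub = c(0, rep(1000, 4)),
                       tags = c("exchange", "transport", "", "", "biomass"),
                       stringsAsFactors = FALSE)
    S <- matrix(0, 3, 5, dimnames = list(mets$id, rxns$id))
    S["a_e", "EX_a"] <- -1
    S["a_e", "T_a"] <- -1; S["a", "T_a"] <- 1
    S["a", "P1"] <- -1; S["b", "P1"] <- 1
    S["a", "P2"] <- -1; S["b", "P2"] <- 1
    S["b", "BIO"] <- -1
    metabolicModel(mets, rxns, S, objective = "BIO")
}

## random small stoichiometric LPs with zero always feasible
randomSmallModel <- function(seed) {
    set.seed(seed)
    nm <- sample(2:6, 1)
    nr <- sample(3:12, 1)
    repeat {
        S <- matrix(stats::rpois(nm * nr, 0.8) *
                        sample(c(-1, 1), nm * nr, TRUE), nm, nr)
        if (all(colSums(S != 0) > 0)) break
    }
    dimnames(S) <- list(paste0("m", seq_len(nm)), paste0("r", seq_len(nr)))
    mets <- data.frame(id = rownames(S), stringsAsFactors = FALSE)
    rxns <- data.frame(id = colnames(S),
                       lb = round(stats::runif(nr, -10, 0), 2),
                       ub = round(stats::runif(nr, 0, 10), 2),
                       stringsAsFactors = FALSE)
    metabolicModel(mets, rxns, S, objective = colnames(S)[nr])
}

## a Level 2 SBML file with kinetic-law bounds and note-encoded GPRs
legacySBMLFile <- function(gpr = "(g1 and g2) or g3",
                           lower = -5, upper = 8) {
    txt <- sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="legacy">
    <listOfCompartments>
      <compartment id="Cytosol"/>
      <compartment id="Extracellular"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_ext" compartment="Extracellular"/>
      <species id="A" compartment="Cytosol"/>
      <species id="B" compartment="Cytosol"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" reversible="true">
        <listOfReactants>
          <speciesReference species="A_ext" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="%s"/>
            <parameter id="UPPER_BOUND" value="%s"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="T_A" reversible="false">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: %s</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="A_ext" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="BIOMASS_legacy" reversible="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="2"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_B" reversible="false">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', lower, upper, gpr)
    f <- tempfile(fileext = ".xml")
    writeLines(txt, f)
    f
}
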