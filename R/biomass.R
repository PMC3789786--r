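## Biomass construction: two biomass pseudo-reactions (with and without
## bacteriochlorophyll a) assembled from macromolecule mass fractions,
## per-polymer monomer composition, and ATP maintenance terms.

#' Default macromolecule mass fractions of dry weight
#'
#' Experimentally determined composition of an exponentially growing
#' culture: protein 45.34%, DNA 3.22%, RNA 4.11%, lipids 14.02%,
#' polyhydroxybutyrate 24.70%, bacteriochlorophyll a 0.08%,
#' lipopolysaccharides 4.00%, peptidoglycan 2.50%, components of
#' unknown identity 0.10%; the soluble pool takes the exact remainder
#' (0.0193 by summation; tabulations that print 1.91% carry a 0.02%
#' rounding discrepancy, which this function does not reproduce).
#' @export
defaultMacroFractions <- function() {
    f <- c(protein = 0.4534, dna = 0.0322, rna = 0.0411, lipids = 0.1402,
           phb = 0.2470, bchl = 0.0008, lps = 0.0400,
           peptidoglycan = 0.0250, unknown = 0.0010)
    c(f, soluble = remainderFraction(f))
}

#' Remaining mass fraction after the listed components
#'
#' @param fractions named numeric of mass fractions (without the
#'   soluble pool).
#' @return 1 minus their sum.
#' @export
remainderFraction <- function(fractions) {
    s <- sum(fractions)
    if (s > 1 + 1e-12) stop("fractions sum to ", s, ", more than 1")
    1 - s
}

#' Construct a BiomassSpec
#'
#' @param macroFractions named mass fractions summing to 1 (within
#'   printed rounding, 5e-3); see [defaultMacroFractions()].
#' @param monomerFractions named list: per macromolecule, a named
#'   vector of monomer shares summing to 1.
#' @param monomerMasses named numeric, residue mass per monomer in
#'   g/mmol (polymerized, water-subtracted, so that polymer mass
#'   accounting closes).
#' @param gam growth-associated ATP maintenance, mmol/gDW.
#' @param ngam non-growth-associated ATP maintenance, mmol/(gDW h);
#'   implemented as a standalone always-on ATP hydrolysis so that it
#'   binds even at zero growth.
#' @param bchlPerProtein bacteriochlorophyll term, mmol per mg protein
#'   (default 4 nmol/mg).
#' @return a [BiomassSpec-class].
#' @export
biomassSpec <- function(macroFractions = defaultMacroFractions(),
                        monomerFractions, monomerMasses,
                        gam = 53.95, ngam = 3.15,
                        bchlPerProtein = 4e-6) {
    new("BiomassSpec", macroFractions = macroFractions,
        monomerFractions = monomerFractions,
        monomerMasses = monomerMasses, gam = gam, ngam = ngam,
        bchlPerProtein = bchlPerProtein)
}

#' Build the two biomass reactions from a composition spec
#'
#' Monomer coefficients are fraction / residue-mass x monomer share, in
#' mmol per gDW, so that consumed monomer mass sums to one gram per
#' gram dry weight. Both variants carry the growth-associated
#' maintenance term (GAM: ATP + H2O -> ADP + Pi + H+); the
#' bacteriochlorophyll variant additionally consumes bchl in proportion
#' to the protein content (mmol bchl = bchlPerProtein x mg protein).
#' Aerobic anoxygenic phototrophs only synthesize bacteriochlorophyll a
#' in the dark under aerobic conditions, hence the pair.
#'
#' @param spec a [BiomassSpec-class]; macromolecule names in
#'   \code{monomerFractions} must match \code{macroFractions} (the
#'   "bchl" fraction needs no monomer table).
#' @param catalog mapping from monomer name to metabolite id: a named
#'   character vector; monomers absent from it are an error.
#' @param energyIds named character vector with metabolite ids for
#'   \code{atp}, \code{h2o}, \code{adp}, \code{pi}, \code{h}.
#' @param bchlId metabolite id of bacteriochlorophyll a.
#' @param ids reaction ids for the bchl-free and bchl variants.
#' @return list of two reaction descriptors (\code{plain},
#'   \code{bchl}), each with elements \code{id}, \code{name},
#'   \code{stoich} (named numeric), \code{lb}, \code{ub}, \code{tags},
#'   and \code{massPerGDW}, the consumed monomer mass (g/gDW, GAM
#'   water excluded).
#' @export
buildBiomassReactions <- function(spec, catalog, energyIds, bchlId,
                                  ids = c("BIOMASS", "BIOMASS_BCHL")) {
    stopifnot(is(spec, "BiomassSpec"))
    validObject(spec)
    f <- spec@macroFractions
    stoich <- numeric(0)
    mass <- 0
    add <- function(st, met, coef) {
        st[met] <- (if (met %in% names(st)) st[[met]] else 0) + coef
        st
    }
    for (macro in setdiff(names(f), c("bchl"))) {
        if (f[[macro]] == 0) next
        mf <- spec@monomerFractions[[macro]]
        if (is.null(mf))
            stop("no monomer composition for macromolecule: ", macro)
        for (mono in names(mf)) {
            met <- if (mono %in% names(catalog)) catalog[[mono]] else NA
            if (is.na(met))
                stop("monomer without catalog metabolite: ", mono)
            m <- spec@monomerMasses[[mono]]
            coef <- f[[macro]] * mf[[mono]] / m
            stoich <- add(stoich, met, -coef)
            mass <- mass + coef * m
        }
    }
    ## growth-associated maintenance
    g <- spec@gam
    stoich <- add(stoich, energyIds[["atp"]], -g)
    stoich <- add(stoich, energyIds[["h2o"]], -g)
    stoich <- add(stoich, energyIds[["adp"]], g)
    stoich <- add(stoich, energyIds[["pi"]], g)
    stoich <- add(stoich, energyIds[["h"]], g)
    plain <- list(id = ids[1], name = "biomass (no bacteriochlorophyll)",
                  stoich = stoich, lb = 0, ub = Inf, tags = "biomass",
                  massPerGDW = mass)
    bchl_coef <- spec@bchlPerProtein * f[["protein"]] * 1000  # mmol/gDW
    bst <- add(stoich, bchlId, -bchl_coef)
    bchl <- list(id = ids[2], name = "biomass (with bacteriochlorophyll)",
                 stoich = bst, lb = 0, ub = Inf, tags = "biomass",
                 massPerGDW = mass)  # bchl mass rides on the protein term
    list(plain = plain, bchl = bchl)
}

## standard genetic code, codon -> one-letter amino acid (stop = "*")
GENETIC_CODE_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

#' Monomer mole fractions estimated from genome composition
#'
#' DNA fractions come from the base counts of both strands (hence
#' dA = dT and dG = dC by strand symmetry); RNA fractions from the
#' transcribed (coding-strand) counts with U replacing T; amino acid
#' fractions from translating the supplied codon usage with the
#' standard genetic code (stop codons ignored).
#'
#' @param baseCounts named numeric, counts of A, C, G, T on one strand.
#' @param codonUsage named numeric, counts per codon (names are DNA
#'   triplets of the coding strand).
#' @return list with named fraction vectors \code{dna} (dA,dC,dG,dT),
#'   \code{rna} (A,C,G,U) and \code{protein} (one-letter amino acids).
#' @export
monomerFractionsFromGenome <- function(baseCounts, codonUsage) {
    need <- c("A", "C", "G", "T")
    if (!all(need %in% names(baseCounts)) || any(baseCounts[need] < 0) ||
        sum(baseCounts[need]) <= 0)
        stop("baseCounts must contain positive counts for A, C, G, T")
    b <- baseCounts[need]
    both <- c(A = (b[["A"]] + b[["T"]]) / 2, C = (b[["C"]] + b[["G"]]) / 2,
              G = (b[["C"]] + b[["G"]]) / 2, T = (b[["A"]] + b[["T"]]) / 2)
    dna <- stats::setNames(as.numeric(both / sum(both)),
                           c("dA", "dC", "dG", "dT"))
    rna <- stats::setNames(as.numeric(b / sum(b)), c("A", "C", "G", "U"))
    aa <- NULL
    if (!missing(codonUsage) && length(codonUsage)) {
        cu <- codonUsage[names(codonUsage) %in% names(GENETIC_CODE_TABLE)]
        aas <- GENETIC_CODE_TABLE[names(cu)]
        keep <- aas != "*"
        tot <- tapply(as.numeric(cu[keep]), aas[keep], sum)
        aa <- stats::setNames(as.numeric(tot / sum(tot)), names(tot))
    }
    list(dna = dna, rna = rna, protein = aa)
}
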