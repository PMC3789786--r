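#' @import methods
NULL

VALID_COMPARTMENTS <- c("c", "e")

#' MetabolicModel: a constraint-based stoichiometric network
#'
#' Central container of the package. Metabolites and reactions are kept
#' as data frames, the stoichiometry as a sparse metabolite-by-reaction
#' matrix, genes with an optional replicon tag (chromosome or a named
#' plasmid), and a single objective reaction whose flux is maximized.
#'
#' Compartments follow a two-compartment convention: \code{"c"} for the
#' cytosol and \code{"e"} for the shared external/periplasmic pool (the
#' proton-motive force lives across this boundary).
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} ("c" or "e"), \code{formula} (character such as
#'   "C6H12O6", NA when unknown, "" for massless species like photons)
#'   and \code{charge} (integer, may be NA).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lb}, \code{ub} (flux bounds, mmol/(gDW h)), \code{gpr}
#'   (boolean gene association string, "" when none) and \code{tags}
#'   (comma-separated labels such as "exchange", "sink", "transport",
#'   "biomass", "proton_translocating", "photosystem", "motility").
#' @slot stoichiometry sparse dgCMatrix, metabolites x reactions;
#'   negative coefficients are consumed species.
#' @slot genes data.frame with columns \code{id} and \code{replicon}.
#' @slot objective character, the id of the objective reaction.
#'
#' @seealso [metabolicModel()], [solveFBA()], [readSBML()]
#' @export
setClass("MetabolicModel",
         representation(metabolites  = "data.frame",
                        reactions    = "data.frame",
                        stoichiometry = "Matrix",
                        genes        = "data.frame",
                        objective    = "character"))

setValidity("MetabolicModel", function(object) {
    msg <- character()
    met <- object@metabolites; rxn <- object@reactions
    if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
    if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
    if (!all(met$compartment %in% VALID_COMPARTMENTS))
        msg <- c(msg, "compartment must be one of 'c' (cytosol), 'e' (external/periplasm)")
    if (any(rxn$lb > rxn$ub)) {
        bad <- rxn$id[rxn$lb > rxn$ub]
        msg <- c(msg, paste0("lower bound exceeds upper bound for: ",
                             paste(bad, collapse = ", ")))
    }
    S <- object@stoichiometry
    if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
        msg <- c(msg, "stoichiometry dimensions do not match metabolites/reactions")
    else {
        if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
            msg <- c(msg, "stoichiometry dimnames must equal metabolite and reaction ids")
        empty <- Matrix::colSums(S != 0) == 0
        if (any(empty))
            msg <- c(msg, paste0("reactions with empty stoichiometry: ",
                                 paste(rxn$id[empty], collapse = ", ")))
    }
    if (length(object@objective) != 1L || !(object@objective %in% rxn$id))
        msg <- c(msg, "objective must name exactly one existing reaction")
    gpr_genes <- unique(unlist(lapply(rxn$gpr, gprGenes)))
    missing <- setdiff(gpr_genes, object@genes$id)
    if (length(missing))
        msg <- c(msg, paste0("GPR references undeclared genes: ",
                             paste(missing, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' FluxSolution: result of one flux balance optimization
#'
#' @slot status one of "optimal", "infeasible", "unbounded",
#'   "solver_failure".
#' @slot objectiveValue optimal objective flux (growth rate, 1/h, when
#'   the objective is a biomass reaction); NA unless optimal.
#' @slot fluxes named numeric vector of fluxes in mmol/(gDW h); empty
#'   unless optimal.
#' @export
setClass("FluxSolution",
         representation(status = "character",
                        objectiveValue = "numeric",
                        fluxes = "numeric"))

#' BiomassSpec: biomass composition and maintenance parameters
#'
#' Macromolecule mass fractions, per-polymer monomer mole fractions and
#' residue masses, the growth-associated (GAM) and non-growth-associated
#' (nGAM) ATP maintenance terms, and the bacteriochlorophyll-per-protein
#' coefficient used for the photoheterotrophic biomass variant.
#'
#' @slot macroFractions named numeric, mass fraction of dry weight per
#'   macromolecule class (includes the soluble-pool remainder).
#' @slot monomerFractions named list; per macromolecule a named numeric
#'   vector of monomer mole fractions summing to 1.
#' @slot monomerMasses named numeric, polymerized residue mass of each
#'   monomer in g/mmol.
#' @slot gam growth-associated maintenance, mmol ATP per gDW.
#' @slot ngam non-growth-associated maintenance, mmol ATP/(gDW h).
#' @slot bchlPerProtein bacteriochlorophyll a term, mmol per mg protein.
#' @export
setClass("BiomassSpec",
         representation(macroFractions = "numeric",
                        monomerFractions = "list",
                        monomerMasses = "numeric",
                        gam = "numeric",
                        ngam = "numeric",
                        bchlPerProtein = "numeric"))

setValidity("BiomassSpec", function(object) {
    msg <- character()
    f <- object@macroFractions
    if (any(f < 0 | f > 1)) msg <- c(msg, "macro fractions must lie in [0, 1]")
    if (abs(sum(f) - 1) > 5e-3)
        msg <- c(msg, sprintf("macro fractions sum to %.4f, not 1 within 5e-3", sum(f)))
    for (poly in names(object@monomerFractions)) {
        mf <- object@monomerFractions[[poly]]
        if (abs(sum(mf) - 1) > 1e-6)
            msg <- c(msg, paste0("monomer fractions of ", poly, " do not sum to 1"))
        unknown <- setdiff(names(mf), names(object@monomerMasses))
        if (length(unknown))
            msg <- c(msg, paste0("monomers without residue mass: ",
                                 paste(unknown, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})
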