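## Small didactic models used in examples, tests and the respiratory
## energetics check.

#' Minimal three-reaction chain model
#'
#' One exchange (uptake capped at 10), one conversion, one biomass
#' drain: the FBA optimum equals the uptake cap and the solution is
#' unique, making the model a convenient fixture.
#' @param cap uptake bound, mmol/(gDW h).
#' @export
exampleChainModel <- function(cap = 10) {
    mets <- data.frame(id = c("a_e", "a", "b"),
                       compartment = c("e", "c", "c"),
                       formula = c("C1", "C1", "C1"),
                       stringsAsFactors = FALSE)
    rxns <- data.frame(id = c("EX_a", "T_a", "BIO"),
                       lb = c(-cap, 0, 0), ub = c(0, 1000, 1000),
                       tags = c("exchange", "transport", "biomass"),
                       stringsAsFactors = FALSE)
    S <- matrix(0, 3, 3, dimnames = list(mets$id, rxns$id))
    S["a_e", "EX_a"] <- -1
    S["a_e", "T_a"] <- -1; S["a", "T_a"] <- 1
    S["a", "BIO"] <- -1
    metabolicModel(mets, rxns, S, objective = "BIO")
}

#' Respiratory electron-transport toy model
#'
#' The proton-translocating reactions of the oxidative phosphorylation
#' (NADH:ubiquinone reductase, ubiquinol-cytochrome-c reductase,
#' cytochrome-c oxidase, and the H+-transporting two-sector ATPase) at
#' their literature stoichiometries, fed by an NADH source and drained
#' by an ATP demand. Following the chain, one NADH exports 10 protons
#' (4 + 4 + 2) and the ATPase consumes 4 per ATP, so the maximal ATP
#' yield per NADH is exactly 2.5.
#'
#' @param nadhBound NADH supply rate, mmol/(gDW h).
#' @export
electronChainModel <- function(nadhBound = 1) {
    mets <- data.frame(
        id = c("nadh", "nad", "q", "qh2", "cytox", "cytred",
               "h", "h_e", "o2", "h2o", "atp", "adp", "pi"),
        compartment = c(rep("c", 7), "e", rep("c", 5)),
        formula = c("C21H27N7O14P2", "C21H26N7O14P2", "C49H74O4",
                    "C49H76O4", "Fe", "Fe", "H", "H", "O2", "H2O",
                    "C10H12N5O13P3", "C10H12N5O10P2", "HO4P"),
        stringsAsFactors = FALSE)
    rx <- list(
        ## boundary supply/drain (exchange-tagged, balance exempt)
        SRC_NADH = list(st = c(nadh = 1, nad = -1), lb = 0, ub = nadhBound,
                        tags = "exchange"),
        SRC_H    = list(st = c(h = 1), lb = -1000, ub = 1000, tags = "exchange"),
        EX_O2    = list(st = c(o2 = -1), lb = -1000, ub = 0, tags = "exchange"),
        EX_H2O   = list(st = c(h2o = -1), lb = 0, ub = 1000, tags = "exchange"),
        ## export-only: the proton-motive force is built by the pumps,
        ## never by free periplasmic proton influx
        EX_HE    = list(st = c(h_e = -1), lb = 0, ub = 1000, tags = "exchange"),
        ## Table of proton-translocating stoichiometries
        NDH  = list(st = c(nadh = -1, h = -5, q = -1, nad = 1, qh2 = 1, h_e = 4),
                    lb = -1000, ub = 1000, tags = "proton_translocating"),
        BC1  = list(st = c(qh2 = -1, cytox = -2, h = -2, q = 1, cytred = 2, h_e = 4),
                    lb = 0, ub = 1000, tags = "proton_translocating"),
        COX  = list(st = c(h = -8, o2 = -1, cytred = -4, h2o = 2, cytox = 4, h_e = 4),
                    lb = 0, ub = 1000, tags = "proton_translocating"),
        ATPS = list(st = c(atp = -1, h = -3, h2o = -1, adp = 1, pi = 1, h_e = 4),
                    lb = -1000, ub = 1000, tags = "proton_translocating"),
        ## ATP demand: hydrolysis drain, the objective
        ATPD = list(st = c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1),
                    lb = 0, ub = 1000, tags = "maintenance"))
    rxns <- data.frame(id = names(rx),
                       lb = vapply(rx, `[[`, 0, "lb"),
                       ub = vapply(rx, `[[`, 0, "ub"),
                       tags = vapply(rx, `[[`, "", "tags"),
                       stringsAsFactors = FALSE)
    S <- matrix(0, nrow(mets), length(rx),
                dimnames = list(mets$id, names(rx)))
    for (j in seq_along(rx))
        S[names(rx[[j]]$st), j] <- rx[[j]]$st
    metabolicModel(mets, rxns, S, objective = "ATPD")
}
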