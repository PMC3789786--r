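## Headline analyses on top of the campaign machinery: DMSP pathway
## partitioning, DMS-overproduction screening, aerobic denitrification
## detection, branch-point flux reports, knockout phenotype classes.

.one_tagged <- function(model, tag) {
    r <- taggedReactions(model, tag)
    if (!length(r)) stop("model has no reaction tagged '", tag, "'")
    r
}

#' Share of DMSP degraded by the demethylation pathway
#'
#' For a DMSP-fed state, the fraction of DMSP uptake routed through the
#' demethylase (tag "demethylation") rather than the cleavage lyases,
#' with min/max taken from FVA at optimal growth — a single optimal
#' flux vector is not trustworthy for a degenerate branch point.
#'
#' @param model a MetabolicModel with "demethylation" and
#'   "dmsp_exchange"-tagged reactions.
#' @param state a DMSP state (one row of [enumerateStates()]).
#' @param ... passed to [applyState()].
#' @param backend LP backend.
#' @return list with \code{minFraction}, \code{maxFraction} (in
#'   [0, 1]), \code{uptake} (mmol/(gDW h)), \code{growth} and
#'   \code{zeroGrowth}.
#' @export
demethylationContribution <- function(model, state,
                                      backend = c("dense", "boot"), ...) {
    backend <- match.arg(backend)
    if (state$carbon_source != "DMSP")
        stop("state's carbon source must be DMSP")
    dem <- .one_tagged(model, "demethylation")[1]
    ex <- .one_tagged(model, "dmsp_exchange")[1]
    m2 <- applyState(model, state, ...)
    sol <- solveFBA(m2, backend = backend)
    if (sol@status != "optimal" || sol@objectiveValue <= ZERO_TOL)
        return(list(minFraction = 0, maxFraction = 0, uptake = 0,
                    growth = 0, zeroGrowth = TRUE))
    uptake <- -sol@fluxes[[ex]]
    fv <- fluxVariability(m2, 1, dem, backend = backend)
    list(minFraction = max(0, min(1, fv$min / uptake)),
         maxFraction = max(0, min(1, fv$max / uptake)),
         uptake = uptake, growth = sol@objectiveValue,
         zeroGrowth = FALSE)
}

#' Screen knockouts for elevated DMS production
#'
#' For each candidate gene and state, compares the mutant's maximal DMS
#' export (FVA maximum at the mutant's optimal growth) against the wild
#' type's. The DMSO reductase also makes DMS, so it is force-closed
#' throughout — all reported DMS then originates from DMSP. Genes whose
#' loss changes neither growth nor DMS are omitted; hits are sorted by
#' DMS gain.
#'
#' @param model a MetabolicModel.
#' @param states data.frame of states (should not rely on DMSO
#'   respiration, which is closed here).
#' @param candidateGenes gene ids to knock out one at a time.
#' @param tol relative tolerance for "unchanged".
#' @param backend,... as elsewhere.
#' @return data.frame with columns \code{gene}, \code{state} (row
#'   index), \code{dmsGain} (percent change of maximal DMS export),
#'   \code{relativeGrowth} (mutant growth as percent of wild type),
#'   \code{wtDmsMin}, \code{wtDmsMax}, \code{mutDmsMin},
#'   \code{mutDmsMax}.
#' @export
dmsOverproductionScreen <- function(model, states, candidateGenes,
                                    tol = 1e-4,
                                    backend = c("dense", "boot"), ...) {
    backend <- match.arg(backend)
    dms_ex <- .one_tagged(model, "dms_exchange")[1]
    dmso_r <- taggedReactions(model, "dmso_reductase")
    out <- list()
    for (si in seq_len(nrow(states))) {
        m0 <- applyState(model, states[si, ], ...)
        if (length(dmso_r)) m0 <- setBounds(m0, dmso_r, lb = 0, ub = 0)
        wt <- solveFBA(m0, backend = backend)
        if (wt@status != "optimal" || wt@objectiveValue <= ZERO_TOL) next
        wt_fv <- fluxVariability(m0, 1, dms_ex, backend = backend)
        for (g in candidateGenes) {
            m1 <- applyKnockouts(m0, g)
            mu <- solveFBA(m1, backend = backend)
            if (mu@status != "optimal") {
                out[[length(out) + 1]] <- data.frame(
                    gene = g, state = si, dmsGain = -100,
                    relativeGrowth = 0, wtDmsMin = wt_fv$min,
                    wtDmsMax = wt_fv$max, mutDmsMin = 0, mutDmsMax = 0,
                    stringsAsFactors = FALSE)
                next
            }
            mu_fv <- if (mu@objectiveValue > ZERO_TOL)
                fluxVariability(m1, 1, dms_ex, backend = backend)
            else data.frame(min = 0, max = 0)
            relg <- 100 * mu@objectiveValue / wt@objectiveValue
            gain <- if (wt_fv$max > ZERO_TOL)
                100 * (mu_fv$max - wt_fv$max) / wt_fv$max
            else if (mu_fv$max > ZERO_TOL) Inf else 0
            unchanged <- abs(relg - 100) < 100 * tol &&
                abs(mu_fv$max - wt_fv$max) <=
                    tol * max(1, abs(wt_fv$max))
            if (unchanged) next
            out[[length(out) + 1]] <- data.frame(
                gene = g, state = si, dmsGain = gain,
                relativeGrowth = relg, wtDmsMin = wt_fv$min,
                wtDmsMax = wt_fv$max, mutDmsMin = mu_fv$min,
                mutDmsMax = mu_fv$max, stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(gene = character(), state = integer(),
                          dmsGain = numeric(), relativeGrowth = numeric(),
                          wtDmsMin = numeric(), wtDmsMax = numeric(),
                          mutDmsMin = numeric(), mutDmsMax = numeric(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res[order(-res$dmsGain), , drop = FALSE]
}

#' States permitting aerobic denitrification
#'
#' Among states offering both oxygen and nitrate, finds those whose
#' optimal face admits simultaneous use of the two acceptors: the FVA
#' maximum of respiratory nitrate reduction (tag
#' "respiratory_nitrate"; assimilatory drawdown is excluded by
#' tagging) exceeds tolerance while the minimal oxygen uptake stays
#' positive. In the dark every proton pumped matters and nitrate
#' respiration is strictly wasteful, so only illuminated states — with
#' photosynthetically covered energy demand and excess reducing
#' equivalents to dispose of — qualify.
#'
#' @param model a MetabolicModel.
#' @param states data.frame; every row must have e_acceptors "O2+NO3".
#' @param tol flux threshold.
#' @param backend,... as elsewhere.
#' @return logical vector along the rows of \code{states}.
#' @export
aerobicDenitrificationStates <- function(model, states, tol = ZERO_TOL,
                                         backend = c("dense", "boot"),
                                         ...) {
    backend <- match.arg(backend)
    if (!all(states$e_acceptors == "O2+NO3"))
        stop("every state must offer O2 and NO3 as electron acceptors")
    resp <- .one_tagged(model, "respiratory_nitrate")
    o2 <- "EX_o2_e"
    vapply(seq_len(nrow(states)), function(si) {
        m2 <- applyState(model, states[si, ], ...)
        sol <- solveFBA(m2, backend = backend)
        if (sol@status != "optimal" || sol@objectiveValue <= ZERO_TOL)
            return(FALSE)
        fv <- fluxVariability(m2, 1, c(resp, o2), backend = backend)
        nitrate_max <- max(fv$max[fv$id %in% resp])
        o2_uptake_min <- -fv$max[fv$id == o2]  # uptake is negative flux
        nitrate_max > tol && o2_uptake_min > tol
    }, logical(1))
}

#' Producer/consumer report at a metabolic branch point
#'
#' The total flux through a metabolite is the sum of producing fluxes
#' (equal to the consuming sum at steady state); each active reaction
#' is listed with its percentage of that total.
#'
#' @param solution an optimal [FluxSolution-class].
#' @param model the model it was computed on.
#' @param metabolite metabolite id.
#' @param tol fluxes below this are not listed.
#' @return list with \code{metabolite}, \code{total} and a data.frame
#'   \code{table} (reaction, flux through the metabolite, side,
#'   percent). An unused metabolite gives total 0 and an empty table.
#' @export
branchPointReport <- function(solution, model, metabolite,
                              tol = ZERO_TOL) {
    stopifnot(solution@status == "optimal")
    i <- match(metabolite, model@metabolites$id)
    if (is.na(i)) stop("unknown metabolite: ", metabolite)
    coef <- as.numeric(model@stoichiometry[i, ])
    v <- solution@fluxes[model@reactions$id]
    thru <- coef * v
    act <- which(abs(thru) > tol)
    if (!length(act))
        return(list(metabolite = metabolite, total = 0,
                    table = data.frame(reaction = character(),
                                       flux = numeric(),
                                       side = character(),
                                       percent = numeric(),
                                       stringsAsFactors = FALSE)))
    total <- sum(thru[act][thru[act] > 0])
    tab <- data.frame(reaction = model@reactions$id[act],
                      flux = thru[act],
                      side = ifelse(thru[act] > 0, "producer", "consumer"),
                      percent = 100 * abs(thru[act]) / total,
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$side, -tab$percent), , drop = FALSE]
    rownames(tab) <- NULL
    list(metabolite = metabolite, total = total, table = tab)
}

#' Classify single-gene knockout phenotypes over a state list
#'
#' Requires a campaign containing a "wildtype" genotype plus one
#' genotype per gene (labelled by gene id). Classes: \code{no_effect}
#' (growth equals wild type in every state, within relative
#' tolerance), \code{always_lethal} (no growth in every state where
#' the wild type grows), \code{multifaceted} (anything else, e.g.
#' lethal only anaerobically). Also returns class percentages and a
#' gene x state growth-category matrix ("unchanged", "reduced",
#' "lethal", "increased"; states where the wild type does not grow are
#' "unchanged" unless the mutant grows).
#'
#' @param campaign a CampaignResult from [runCampaign()].
#' @param tol relative growth-equality tolerance.
#' @return list with \code{classes} (data.frame gene, class),
#'   \code{fractions} (named percentages summing to 100) and
#'   \code{matrix}.
#' @export
classifyKnockoutPhenotypes <- function(campaign, tol = 1e-4) {
    rec <- campaign$records
    if (!"wildtype" %in% rec$genotype)
        stop("campaign lacks a 'wildtype' genotype as reference")
    wt <- rec[rec$genotype == "wildtype", ]
    genes <- setdiff(unique(rec$genotype), "wildtype")
    nst <- nrow(wt)
    cat_mat <- matrix("unchanged", length(genes), nst,
                      dimnames = list(genes, NULL))
    cls <- character(length(genes))
    for (k in seq_along(genes)) {
        mu <- rec[rec$genotype == genes[k], ]
        if (nrow(mu) != nst) stop("gene ", genes[k],
                                  " was not simulated over every state")
        wtg <- wt$growth; mug <- mu$growth
        eq <- abs(mug - wtg) <= tol * pmax(wtg, ZERO_TOL)
        lethal <- mug <= ZERO_TOL & wtg > ZERO_TOL
        cat_mat[k, lethal] <- "lethal"
        cat_mat[k, !lethal & !eq & mug < wtg] <- "reduced"
        cat_mat[k, !lethal & !eq & mug > wtg] <- "increased"
        cls[k] <- if (all(eq)) "no_effect"
        else if (all(mug[wtg > ZERO_TOL] <= ZERO_TOL)) "always_lethal"
        else "multifaceted"
    }
    frac <- 100 * table(factor(cls, levels = c("no_effect",
                                               "always_lethal",
                                               "multifaceted"))) /
        max(1, length(cls))
    list(classes = data.frame(gene = genes, class = cls,
                              stringsAsFactors = FALSE),
         fractions = stats::setNames(as.numeric(frac), names(frac)),
         matrix = cat_mat)
}
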