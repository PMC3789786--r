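## Physiological-state grid: enumeration, translation into model
## bounds, campaign execution and flux-distribution grouping.

#' The default condition grid
#'
#' 26 carbon sources x 3 nitrogen sources x 5 electron-acceptor sets x
#' 3 carbon-atom uptake tiers x 2 illumination levels x 3 motile
#' fractions = 7,020 physiological states. Uptake tiers are in mmol
#' carbon atoms/(gDW h): 1 (oligotrophic), 12 (glucose-derived), 39.2
#' (succinate-derived). Illumination is the photon uptake bound in
#' mmol/(gDW h); 34.6 in the light (33.8 is an accepted alternative
#' calibration), 0 in the dark.
#'
#' @export
defaultStateGrid <- function() {
    list(carbon_source = defaultCarbonSources()$source,
         n_source = c("ammonia", "urea", "nitrate"),
         e_acceptors = c("O2", "NO3", "DMSO", "O2+NO3", "O2+DMSO"),
         uptake_tier = c(1, 12, 39.2),
         illumination = c(34.6, 0),
         motile_fraction = c(0, 0.1, 0.2))
}

#' Carbon sources with exchange reactions and carbon counts
#'
#' @return data.frame with columns \code{source}, \code{exchange} (the
#'   exchange reaction id in the synthetic core model) and
#'   \code{carbons}.
#' @export
defaultCarbonSources <- function() {
    data.frame(source = names(.carbon_sources),
               exchange = vapply(.carbon_sources, function(x)
                   paste0("EX_", x$met, "_e"), ""),
               carbons = vapply(.carbon_sources, `[[`, 0, "C"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Enumerate the full cross-product of a condition grid
#'
#' @param grid named list of per-parameter value vectors (see
#'   [defaultStateGrid()]); every entry must be non-empty.
#' @return data.frame with one row per state, in deterministic
#'   lexicographic order (first parameter varies slowest).
#' @export
enumerateStates <- function(grid = defaultStateGrid()) {
    if (!length(grid) || any(!lengths(grid)))
        stop("every grid parameter needs at least one value")
    g <- do.call(expand.grid,
                 c(rev(grid), list(stringsAsFactors = FALSE,
                                   KEEP.OUT.ATTRS = FALSE)))
    g <- g[, rev(seq_along(grid)), drop = FALSE]
    names(g) <- names(grid)
    rownames(g) <- NULL
    g
}

#' Carbon-atom normalized uptake bound
#'
#' Uptake rates are normalized to the number of carbon atoms so that
#' for a given tier the carbon intake per time is the same for every
#' source: bound = tier / carbon count, in mmol/(gDW h).
#'
#' @param source carbon source name (looked up in \code{table}) or a
#'   numeric carbon count.
#' @param tier carbon atoms mmol/(gDW h).
#' @param table as [defaultCarbonSources()].
#' @export
carbonUptakeBound <- function(source, tier, table = defaultCarbonSources()) {
    n <- if (is.numeric(source)) source else {
        i <- match(source, table$source)
        if (is.na(i)) stop("unknown carbon source: ", source)
        table$carbons[i]
    }
    if (n < 1) stop("carbon count must be at least 1")
    tier / n
}

#' Flagellar motor parameters
#'
#' N = 1200 protons per motor rotation, v = 10 rotations/s, cell dry
#' mass 300 fg. The proton drain actually imposed on the model is
#' anchored at the published operating point of 24 mmol/(gDW h) for a
#' 10% motile culture and scales linearly with the motile fraction;
#' [motilityFluxFromPhysics()] exposes the closed-form estimate
#' N v / m (which evaluates to about 0.24 mmol/(gDW h) per unit motile
#' fraction, three orders of magnitude below the anchor) for
#' comparison.
#'
#' @export
motilityParams <- function() {
    list(protonsPerRotation = 1200, rotationsPerSecond = 10,
         cellDryMass = 3e-13,          # g (300 fg)
         referenceFlux = 24)           # mmol/(gDW h) at 10% motile
}

#' @rdname motilityParams
#' @param fraction motile fraction of the culture, in [0, 1].
#' @param params as [motilityParams()].
#' @export
motilityFlux <- function(fraction, params = motilityParams()) {
    if (fraction < 0 || fraction > 1)
        stop("motile fraction must lie in [0, 1]")
    params$referenceFlux * fraction / 0.10
}

#' @rdname motilityParams
#' @export
motilityFluxFromPhysics <- function(fraction, params = motilityParams()) {
    if (fraction < 0 || fraction > 1)
        stop("motile fraction must lie in [0, 1]")
    protons_per_s <- params$protonsPerRotation * params$rotationsPerSecond
    mol_per_g_h <- protons_per_s / params$cellDryMass / 6.02214076e23 * 3600
    mol_per_g_h * 1000 * fraction
}

.state_ids <- list(photon = "EX_photon_e", o2 = "EX_o2_e",
                   no3 = "EX_no3_e", dmso = "EX_dmso_e",
                   nh3 = "EX_nh3_e", urea = "EX_urea_e",
                   motility = "MOTILITY",
                   vitamins = c("EX_biotin_e", "EX_nico_e", "EX_paba_e"),
                   o2rib = "EX_o2rib_e",
                   biomass = c(plain = "BIOMASS", bchl = "BIOMASS_BCHL"))

.acceptor_set <- function(label) strsplit(label, "+", fixed = TRUE)[[1]]

#' Translate a physiological state into model bounds
#'
#' Sets the selected carbon exchange to its carbon-normalized uptake
#' bound and closes all others; opens the nitrogen source and the
#' electron acceptors; sets the photon bound (an upper bound on uptake
#' by default: futile dissipation of excess photons need not be forced
#' through the network); fixes the flagellar proton drain; keeps the
#' vitamin exchanges and the dedicated corrinoid-oxygen exchange open;
#' and selects the biomass variant: bacteriochlorophyll is only made in
#' the dark under aerobic conditions, so that variant becomes the
#' objective exactly then.
#'
#' @param model a MetabolicModel containing the exchanges and both
#'   biomass reactions (a missing reaction is a named error).
#' @param state one row of [enumerateStates()] (or an equivalent list
#'   with the same fields).
#' @param carbonTable as [defaultCarbonSources()].
#' @param photonEquality force photon uptake to equal the illumination
#'   value instead of bounding it.
#' @param photosystemOffAnaerobic close the photon exchange in
#'   anaerobic states (the photosystem may stop without oxygen).
#' @param ids reaction-id map; override for models with other naming.
#' @param vitaminBound uptake bound on vitamin exchanges.
#' @return the constrained model with the appropriate objective.
#' @export
applyState <- function(model, state, carbonTable = defaultCarbonSources(),
                       photonEquality = FALSE,
                       photosystemOffAnaerobic = FALSE,
                       ids = .state_ids, vitaminBound = 10) {
    state <- as.list(state)
    need <- c(ids$o2, ids$no3, ids$dmso, ids$nh3, ids$urea, ids$motility,
              unname(ids$biomass), ids$vitamins, ids$o2rib)
    miss <- setdiff(need, model@reactions$id)
    if (length(miss))
        stop("model lacks required reaction(s): ",
             paste(miss, collapse = ", "))
    acc <- .acceptor_set(state$e_acceptors)

    ## carbon: close all, open the selected source
    i <- match(state$carbon_source, carbonTable$source)
    if (is.na(i)) stop("unknown carbon source: ", state$carbon_source)
    present <- carbonTable$exchange[carbonTable$exchange %in%
                                    model@reactions$id]
    model <- setBounds(model, present, lb = 0, ub = 0)
    cex <- carbonTable$exchange[i]
    if (!cex %in% model@reactions$id)
        stop("model lacks required reaction(s): ", cex)
    model <- setBounds(model, cex,
                       lb = -carbonUptakeBound(state$carbon_source,
                                               state$uptake_tier,
                                               carbonTable),
                       ub = 0)
    ## nitrogen source (nitrate shares its exchange with the acceptor);
    ## uptake only — otherwise nitrate reduction to excreted ammonia
    ## would act as an unintended electron sink
    model <- setBounds(model, c(ids$nh3, ids$urea, ids$no3), lb = 0, ub = 0)
    model <- setBounds(model, switch(state$n_source,
                                     ammonia = ids$nh3, urea = ids$urea,
                                     nitrate = ids$no3,
                                     stop("unknown nitrogen source: ",
                                          state$n_source)),
                       lb = -1000)
    ## electron acceptors
    model <- setBounds(model, ids$o2, lb = if ("O2" %in% acc) -1000 else 0)
    if ("NO3" %in% acc) model <- setBounds(model, ids$no3, lb = -1000)
    model <- setBounds(model, ids$dmso,
                       lb = if ("DMSO" %in% acc) -1000 else 0)
    ## illumination
    photon <- state$illumination
    if (photosystemOffAnaerobic && !("O2" %in% acc)) photon <- 0
    if (ids$photon %in% model@reactions$id)
        model <- setBounds(model, ids$photon, lb = -photon,
                           ub = if (photonEquality) -photon else 0)
    else if (photon > 0)
        stop("model lacks required reaction(s): ", ids$photon)
    ## motility proton drain, fixed
    mot <- motilityFlux(state$motile_fraction)
    model <- setBounds(model, ids$motility, lb = mot, ub = mot)
    ## vitamins and the corrinoid oxygen supply stay open
    model <- setBounds(model, ids$vitamins, lb = -vitaminBound)
    model <- setBounds(model, ids$o2rib, lb = -1000)
    ## biomass variant
    dark_aerobic <- state$illumination == 0 && "O2" %in% acc
    objectiveReaction(model) <- unname(
        if (dark_aerobic) ids$biomass[["bchl"]] else ids$biomass[["plain"]])
    model
}

#' Genotypes: gene knockouts plus reaction toggles
#'
#' @param label genotype name.
#' @param disabledGenes gene ids knocked out.
#' @param disabledReactions reaction ids forced to (0, 0) (e.g. for
#'   screens that must close a route regardless of genetics).
#' @param enabledReactions reaction ids re-opened (e.g. the
#'   phosphofructokinase toggle), given bounds \code{enabledBounds}.
#' @param enabledBounds length-2 numeric.
#' @export
genotype <- function(label, disabledGenes = character(),
                     disabledReactions = character(),
                     enabledReactions = character(),
                     enabledBounds = c(0, 1000)) {
    if (length(intersect(disabledReactions, enabledReactions)))
        stop("a reaction cannot be both disabled and enabled")
    structure(list(label = label, disabledGenes = disabledGenes,
                   disabledReactions = disabledReactions,
                   enabledReactions = enabledReactions,
                   enabledBounds = enabledBounds),
              class = "Genotype")
}

#' @rdname genotype
#' @param model a MetabolicModel.
#' @param g a Genotype.
#' @export
applyGenotype <- function(model, g) {
    stopifnot(inherits(g, "Genotype"))
    model <- applyKnockouts(model, g$disabledGenes)
    if (length(g$disabledReactions))
        model <- setBounds(model, g$disabledReactions, lb = 0, ub = 0)
    if (length(g$enabledReactions))
        model <- setBounds(model, g$enabledReactions,
                           lb = g$enabledBounds[1], ub = g$enabledBounds[2])
    model
}

#' Run a genotype x state simulation campaign
#'
#' One FBA per (genotype, state) cell in deterministic order (genotypes
#' outer, states inner). Infeasible cells — e.g. maintenance plus
#' motility exceeding the available energy — are recorded as growth 0;
#' solver failures are recorded per cell and never abort the campaign.
#'
#' @param model the base model.
#' @param states data.frame from [enumerateStates()].
#' @param genotypes list of [genotype()] objects.
#' @param carbonTable,backend,... passed to [applyState()]/[solveFBA()].
#' @param fva also record FVA ranges (min/max matrices) per cell for
#'   the reactions in \code{fvaReactions}; used for canonicalized
#'   distribution grouping.
#' @param fvaReactions reaction ids for per-cell FVA (default all).
#' @return a \code{CampaignResult}: list with \code{records} (one row
#'   per cell: genotype, the state fields, growth, status, group),
#'   \code{fluxes} (cells x reactions matrix) and optionally
#'   \code{fvaMin}/\code{fvaMax}.
#' @export
runCampaign <- function(model, states, genotypes = list(genotype("wildtype")),
                        carbonTable = defaultCarbonSources(),
                        backend = c("dense", "boot"), fva = FALSE,
                        fvaReactions = NULL, ...) {
    backend <- match.arg(backend)
    ncell <- length(genotypes) * nrow(states)
    ids <- model@reactions$id
    if (is.null(fvaReactions)) fvaReactions <- ids
    flx <- matrix(0, ncell, length(ids), dimnames = list(NULL, ids))
    fmin <- fmax <- if (fva)
        matrix(NA_real_, ncell, length(fvaReactions),
               dimnames = list(NULL, fvaReactions))
    growth <- numeric(ncell); status <- character(ncell)
    glab <- character(ncell); srow <- integer(ncell)
    k <- 0L
    for (gi in seq_along(genotypes)) {
        for (si in seq_len(nrow(states))) {
            k <- k + 1L
            glab[k] <- genotypes[[gi]]$label
            srow[k] <- si
            res <- tryCatch({
                m2 <- applyState(model, states[si, ], carbonTable, ...)
                m2 <- applyGenotype(m2, genotypes[[gi]])
                sol <- solveFBA(m2, backend = backend)
                fv <- if (fva && sol@status == "optimal" &&
                           sol@objectiveValue > ZERO_TOL)
                    fluxVariability(m2, 1, fvaReactions, backend = backend)
                list(sol = sol, fv = fv)
            }, error = function(e) e)
            if (inherits(res, "error")) {
                growth[k] <- NA_real_; status[k] <- "solver_failure"
                next
            }
            sol <- res$sol
            if (sol@status == "optimal") {
                growth[k] <- max(0, sol@objectiveValue)
                status[k] <- "optimal"
                flx[k, ] <- sol@fluxes[ids]
                if (!is.null(res$fv)) {
                    fmin[k, ] <- res$fv$min; fmax[k, ] <- res$fv$max
                }
            } else if (sol@status == "infeasible") {
                growth[k] <- 0; status[k] <- "infeasible"
            } else {
                growth[k] <- NA_real_; status[k] <- sol@status
            }
        }
    }
    records <- cbind(data.frame(genotype = glab, stringsAsFactors = FALSE),
                     states[srow, , drop = FALSE],
                     data.frame(growth = growth, status = status,
                                group = NA_integer_))
    rownames(records) <- NULL
    structure(list(records = records, fluxes = flx,
                   fvaMin = fmin, fvaMax = fmax),
              class = "CampaignResult")
}

#' Group identical flux distributions
#'
#' Two cells fall into the same group when their flux vectors agree to
#' within \code{tol} per reaction. Distinct states often share one
#' distribution: an unused additional nutrient, a knockout backed up by
#' an isozyme, or the all-zero no-growth distribution (typically the
#' most common one). When per-cell FVA ranges are present (see
#' \code{fva} in [runCampaign()]), fluxes of degenerate reactions
#' (range wider than \code{tol}) are first snapped to the FVA midpoint
#' so alternate optima of the same face do not split a group.
#'
#' @param campaign a CampaignResult.
#' @param tol flux comparison tolerance.
#' @return the campaign with \code{records$group} filled (group ids
#'   numbered by first appearance).
#' @export
groupFluxDistributions <- function(campaign, tol = 1e-6) {
    stopifnot(inherits(campaign, "CampaignResult"))
    v <- campaign$fluxes
    if (!is.null(campaign$fvaMin)) {
        ok <- !is.na(campaign$fvaMin[, 1])
        if (any(ok)) {
            lo <- campaign$fvaMin[ok, , drop = FALSE]
            hi <- campaign$fvaMax[ok, , drop = FALSE]
            wide <- (hi - lo) > tol
            mid <- (hi + lo) / 2
            cols <- match(colnames(campaign$fvaMin), colnames(v))
            vv <- v[ok, cols, drop = FALSE]
            vv[wide] <- mid[wide]
            v[ok, cols] <- vv
        }
    }
    key <- apply(round(v / tol), 1, paste, collapse = ",")
    campaign$records$group <- match(key, unique(key))
    campaign
}
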