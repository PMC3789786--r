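## Report writers and structured-config readers: model statistics,
## flux/FVA tables, campaign stores, knockout matrices, biomass and
## campaign configuration files.

#' Write model statistics as JSON or TSV
#'
#' @param model a MetabolicModel.
#' @param path output file.
#' @param format "json" or "tsv".
#' @param blocked optional result of [blockedReactions()] for a
#'   non-blocked count.
#' @export
writeModelStats <- function(model, path, format = c("json", "tsv"),
                            blocked = NULL) {
    format <- match.arg(format)
    stats <- modelStats(model, blocked)
    if (format == "json")
        jsonlite::write_json(stats, path, auto_unbox = TRUE, pretty = TRUE)
    else
        utils::write.table(data.frame(property = names(stats),
                                      value = unlist(stats)),
                           path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(path)
}

#' Write a flux table (optionally with FVA ranges) as TSV
#'
#' @param solution an optimal FluxSolution.
#' @param path output file.
#' @param fva optional data.frame from [fluxVariability()].
#' @export
writeFluxTSV <- function(solution, path, fva = NULL) {
    stopifnot(solution@status == "optimal")
    tab <- data.frame(id = names(solution@fluxes),
                      flux = as.numeric(solution@fluxes),
                      stringsAsFactors = FALSE)
    if (!is.null(fva)) {
        i <- match(tab$id, fva$id)
        tab$min <- fva$min[i]
        tab$max <- fva$max[i]
    }
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write campaign records as TSV plus a compact flux store
#'
#' @param campaign a CampaignResult.
#' @param dir output directory (created if needed); writes
#'   \code{records.tsv} and \code{fluxes.rds}.
#' @export
writeCampaign <- function(campaign, dir) {
    stopifnot(inherits(campaign, "CampaignResult"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(campaign$records, file.path(dir, "records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    saveRDS(campaign$fluxes, file.path(dir, "fluxes.rds"))
    invisible(dir)
}

#' Write the gene x state growth-category matrix as plain text
#'
#' @param classification result of [classifyKnockoutPhenotypes()].
#' @param path output file.
#' @export
writeKnockoutMatrix <- function(classification, path) {
    m <- classification$matrix
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       col.names = NA)
    invisible(path)
}

#' Read a biomass composition spec from a JSON config file
#'
#' Expected keys: \code{macroFractions}, \code{monomerFractions},
#' \code{monomerMasses}, and optionally \code{gam}, \code{ngam},
#' \code{bchlPerProtein}.
#' @param path JSON file.
#' @return a [BiomassSpec-class].
#' @export
readBiomassSpec <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    args <- list(macroFractions = unlist(cfg$macroFractions),
                 monomerFractions = lapply(cfg$monomerFractions, unlist),
                 monomerMasses = unlist(cfg$monomerMasses))
    for (k in c("gam", "ngam", "bchlPerProtein"))
        if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
    do.call(biomassSpec, args)
}

#' Read a campaign configuration from a JSON file
#'
#' Expected keys: \code{grid} (per-parameter value lists) and
#' optionally \code{genotypes} (list of objects with \code{label},
#' \code{disabledGenes}, \code{disabledReactions},
#' \code{enabledReactions}) and \code{tol}.
#' @param path JSON file.
#' @return list with \code{grid}, \code{genotypes}, \code{tol}.
#' @export
readCampaignConfig <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(cfg$grid)) stop("campaign config lacks a 'grid' entry")
    grid <- lapply(cfg$grid, function(x) unlist(x))
    genotypes <- list(genotype("wildtype"))
    if (!is.null(cfg$genotypes)) {
        gl <- cfg$genotypes
        if (is.data.frame(gl)) gl <- split(gl, seq_len(nrow(gl)))
        genotypes <- unname(lapply(gl, function(g)
            genotype(label = g$label,
                     disabledGenes = as.character(unlist(g$disabledGenes)),
                     disabledReactions = as.character(unlist(g$disabledReactions)),
                     enabledReactions = as.character(unlist(g$enabledReactions)))))
    }
    list(grid = grid, genotypes = genotypes,
         tol = if (is.null(cfg$tol)) 1e-6 else cfg$tol)
}

#' Write the generator ground truth as a JSON sidecar
#'
#' @param groundTruth the \code{groundTruth} element of
#'   [generateCoreModel()].
#' @param path output file.
#' @export
writeGroundTruth <- function(groundTruth, path) {
    jsonlite::write_json(groundTruth, path, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}
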