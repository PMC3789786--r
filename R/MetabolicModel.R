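#' Construct a MetabolicModel
#'
#' @param metabolites data.frame with at least an \code{id} column;
#'   missing \code{name}, \code{compartment}, \code{formula},
#'   \code{charge} columns are filled with defaults (compartment "c").
#' @param reactions data.frame with at least \code{id}, \code{lb},
#'   \code{ub}; missing \code{name}, \code{gpr}, \code{tags} filled.
#' @param stoichiometry matrix (dense or sparse), metabolites x
#'   reactions, rows/columns in the order of the two data frames.
#' @param genes data.frame with \code{id} and optional \code{replicon}
#'   column, or a character vector of gene ids. Genes referenced by
#'   GPRs but not listed are added with replicon "chromosome".
#' @param objective id of the objective reaction.
#' @return a validated [MetabolicModel-class].
#' @export
metabolicModel <- function(metabolites, reactions, stoichiometry,
                           genes = character(), objective) {
    metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
    reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
    if (is.null(metabolites$name)) metabolites$name <- metabolites$id
    if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
    if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
    if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
    if (is.null(reactions$name)) reactions$name <- reactions$id
    if (is.null(reactions$gpr)) reactions$gpr <- ""
    if (is.null(reactions$tags)) reactions$tags <- ""
    reactions$gpr[is.na(reactions$gpr)] <- ""
    reactions$tags[is.na(reactions$tags)] <- ""
    rownames(metabolites) <- NULL; rownames(reactions) <- NULL

    if (is.character(genes)) genes <- data.frame(id = genes, stringsAsFactors = FALSE)
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    if (is.null(genes$id)) genes$id <- character()
    if (is.null(genes$replicon)) genes$replicon <- rep("chromosome", nrow(genes))
    gpr_genes <- unique(unlist(lapply(reactions$gpr, gprGenes)))
    extra <- setdiff(gpr_genes, genes$id)
    if (length(extra))
        genes <- rbind(genes, data.frame(id = extra, replicon = "chromosome",
                                         stringsAsFactors = FALSE))
    rownames(genes) <- NULL

    S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    dimnames(S) <- list(metabolites$id, reactions$id)
    new("MetabolicModel", metabolites = metabolites, reactions = reactions,
        stoichiometry = S, genes = genes, objective = objective)
}

## ---- accessors --------------------------------------------------------

#' @rdname metabolicModel
#' @param model,object a MetabolicModel.
#' @export
metabolites <- function(model) model@metabolites

#' @rdname metabolicModel
#' @export
reactions <- function(model) model@reactions

#' @rdname metabolicModel
#' @export
genes <- function(model) model@genes

#' @rdname metabolicModel
#' @export
reactionIds <- function(model) model@reactions$id

#' @rdname metabolicModel
#' @export
metaboliteIds <- function(model) model@metabolites$id

#' @rdname metabolicModel
#' @export
geneIds <- function(model) model@genes$id

#' @rdname metabolicModel
#' @export
nReactions <- function(model) nrow(model@reactions)

#' @rdname metabolicModel
#' @export
nMetabolites <- function(model) nrow(model@metabolites)

#' @rdname metabolicModel
#' @export
nGenes <- function(model) nrow(model@genes)

#' @rdname metabolicModel
#' @export
stoichiometricMatrix <- function(model) model@stoichiometry

#' Flux bounds of one or all reactions
#'
#' @param model a MetabolicModel.
#' @param reaction reaction id(s); NULL for all.
#' @return data.frame with columns id, lb, ub.
#' @export
bounds <- function(model, reaction = NULL) {
    b <- model@reactions[, c("id", "lb", "ub")]
    if (!is.null(reaction)) {
        idx <- match(reaction, b$id)
        if (anyNA(idx)) stop("unknown reaction id(s): ",
                             paste(reaction[is.na(idx)], collapse = ", "))
        b <- b[idx, , drop = FALSE]
    }
    rownames(b) <- NULL
    b
}

#' Set flux bounds on named reactions
#'
#' @param model a MetabolicModel.
#' @param reaction character vector of reaction ids.
#' @param lb,ub new bounds, recycled to the length of \code{reaction};
#'   NA leaves the existing value untouched.
#' @return the modified model (input is not mutated).
#' @export
setBounds <- function(model, reaction, lb = NA, ub = NA) {
    idx <- match(reaction, model@reactions$id)
    if (anyNA(idx)) stop("unknown reaction id(s): ",
                         paste(reaction[is.na(idx)], collapse = ", "))
    lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
    model@reactions$lb[idx] <- ifelse(is.na(lb), model@reactions$lb[idx], lb)
    model@reactions$ub[idx] <- ifelse(is.na(ub), model@reactions$ub[idx], ub)
    model
}

#' @rdname metabolicModel
#' @export
objectiveReaction <- function(model) model@objective

#' @rdname metabolicModel
#' @param value new objective reaction id.
#' @export
`objectiveReaction<-` <- function(model, value) {
    if (!value %in% model@reactions$id) stop("unknown reaction id: ", value)
    model@objective <- value
    model
}

#' Test whether a reaction carries a tag
#'
#' @param model a MetabolicModel.
#' @param reaction reaction id(s).
#' @param tag single tag, e.g. "exchange".
#' @export
hasTag <- function(model, reaction, tag) {
    idx <- match(reaction, model@reactions$id)
    if (anyNA(idx)) stop("unknown reaction id(s): ",
                         paste(reaction[is.na(idx)], collapse = ", "))
    vapply(strsplit(model@reactions$tags[idx], ","),
           function(tt) tag %in% trimws(tt), logical(1))
}

#' @rdname hasTag
#' @export
taggedReactions <- function(model, tag) {
    model@reactions$id[vapply(strsplit(model@reactions$tags, ","),
                              function(tt) tag %in% trimws(tt), logical(1))]
}

setMethod("show", "MetabolicModel", function(object) {
    cat("MetabolicModel\n")
    cat(sprintf("  metabolites: %d   reactions: %d   genes: %d\n",
                nMetabolites(object), nReactions(object), nGenes(object)))
    cat(sprintf("  objective:   %s\n", object@objective))
    repl <- table(object@genes$replicon)
    if (length(repl) > 1)
        cat("  replicons:  ", paste(names(repl), repl, sep = ":", collapse = "  "), "\n")
})

setMethod("show", "FluxSolution", function(object) {
    cat(sprintf("FluxSolution [%s]", object@status))
    if (object@status == "optimal")
        cat(sprintf("  objective = %.6g", object@objectiveValue))
    cat("\n")
})

#' @rdname solveFBA
#' @export
fluxes <- function(solution) solution@fluxes

#' @rdname solveFBA
#' @export
objectiveValue <- function(solution) solution@objectiveValue

#' @rdname solveFBA
#' @export
solutionStatus <- function(solution) solution@status

## ---- formulas and element balance -------------------------------------

#' Parse a chemical formula string into an element count map
#'
#' Elements are one uppercase letter followed by lowercase letters;
#' counts may be fractional (useful for lumped synthetic species). An
#' empty string is a massless species (e.g. a photon) and parses to an
#' empty vector; NA means the formula is unknown.
#'
#' @param formula character scalar.
#' @return named numeric vector of element counts, or NULL if unknown.
#' @export
parseFormula <- function(formula) {
    if (is.na(formula)) return(NULL)
    if (!nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
    m <- gregexpr("([A-Z][a-z]*)([0-9]*\\.?[0-9]*)", formula, perl = TRUE)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(formula))
        stop("cannot parse formula: ", formula)
    el <- sub("^([A-Z][a-z]*).*$", "\\1", toks)
    ct <- sub("^[A-Z][a-z]*", "", toks)
    ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
    out <- tapply(ct, el, sum)
    stats::setNames(as.numeric(out), names(out))
}

#' Standard and pseudo-element atomic masses (g/mol)
#'
#' Includes the pseudo-element "R" used for the coenzyme A moiety of
#' lumped acyl species (assigned the mass of coenzyme A).
#' @export
elementMasses <- function() {
    c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974,
      S = 32.06, Na = 22.990, Mg = 24.305, Fe = 55.845, Co = 58.933,
      R = 766.53)
}

#' Molecular mass of a formula in g/mol
#' @param formula character scalar formula.
#' @param masses named numeric of element masses.
#' @export
formulaMass <- function(formula, masses = elementMasses()) {
    f <- parseFormula(formula)
    if (is.null(f)) return(NA_real_)
    if (!length(f)) return(0)
    unknown <- setdiff(names(f), names(masses))
    if (length(unknown)) stop("no mass for element(s): ",
                              paste(unknown, collapse = ", "))
    sum(f * masses[names(f)])
}

#' Per-element net balance of a reaction
#'
#' Sums coefficient times element count over all participants. An
#' all-zero result means the reaction is mass balanced. Reactions
#' carrying an exemption tag (system-boundary reactions: exchanges,
#' sinks, and the biomass pseudo-reactions) are intentionally
#' unbalanced and are flagged instead of summed. Participants without a
#' formula are reported, not fatal.
#'
#' @param model a MetabolicModel.
#' @param reaction one reaction id.
#' @param exemptTags tags marking balance-exempt reactions.
#' @return list with elements \code{reaction}, \code{exempt} (logical),
#'   \code{net} (named numeric, NULL when exempt) and
#'   \code{missingFormula} (ids of participants without formulas).
#' @export
elementBalance <- function(model, reaction,
                           exemptTags = c("exchange", "sink", "biomass")) {
    j <- match(reaction, model@reactions$id)
    if (is.na(j)) stop("unknown reaction id: ", reaction)
    exempt <- any(vapply(exemptTags, function(t) hasTag(model, reaction, t),
                         logical(1)))
    if (exempt)
        return(list(reaction = reaction, exempt = TRUE, net = NULL,
                    missingFormula = character()))
    col <- model@stoichiometry[, j]
    part <- which(col != 0)
    net <- numeric(0)
    missing <- character()
    for (i in part) {
        f <- parseFormula(model@metabolites$formula[i])
        if (is.null(f)) { missing <- c(missing, model@metabolites$id[i]); next }
        for (el in names(f)) {
            if (!el %in% names(net)) net[el] <- 0
            net[el] <- net[el] + col[i] * f[[el]]
        }
    }
    list(reaction = reaction, exempt = FALSE,
         net = net[order(names(net))], missingFormula = missing)
}

#' @rdname elementBalance
#' @param balance result of `elementBalance()`.
#' @param tol absolute tolerance on net element counts.
#' @export
isBalanced <- function(balance, tol = 1e-6) {
    if (balance$exempt) return(NA)
    if (length(balance$missingFormula)) return(NA)
    !length(balance$net) || all(abs(balance$net) < tol)
}

#' Summary statistics of a model
#'
#' Counts mirroring a model-properties table: metabolites, reactions,
#' genes, and the number of distinct biomass compounds (union of
#' substrate species over all biomass-tagged reactions).
#'
#' @param model a MetabolicModel.
#' @param blocked optionally, the result of [blockedReactions()]; when
#'   supplied a non-blocked count is included.
#' @return named list of counts.
#' @export
modelStats <- function(model, blocked = NULL) {
    bio <- taggedReactions(model, "biomass")
    compounds <- character()
    for (r in bio) {
        col <- model@stoichiometry[, match(r, model@reactions$id)]
        compounds <- union(compounds, model@metabolites$id[col < 0])
    }
    out <- list(metabolites = nMetabolites(model),
                reactions = nReactions(model),
                genes = nGenes(model),
                biomassCompounds = length(compounds))
    if (!is.null(blocked))
        out$nonBlockedReactions <- nReactions(model) - length(blocked)
    out
}
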