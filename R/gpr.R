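#' Gene-protein-reaction (GPR) association logic
#'
#' GPR strings are boolean expressions over gene identifiers, e.g.
#' \code{"(g1 and g2) or g3"}: AND joins subunits of a complex, OR joins
#' isozymes/paralogs. An empty string means no gene is known for the
#' reaction.
#'
#' @param gpr a GPR string, or a tree as returned by `gprParse()`.
#' @return `gprParse()` returns a parse tree (a gene id for a leaf, or
#'   `list(op = "and"/"or", args = list(...))`); `NULL` for an empty
#'   association.
#' @examples
#' gprEvaluate("(g1 or g2)", removed = "g1")   # TRUE, isozyme remains
#' gprEvaluate("(g1 and g2)", removed = "g1")  # FALSE, complex broken
#' @export
gprParse <- function(gpr) {
    if (is.list(gpr) || (is.character(gpr) && length(gpr) == 1 && !nzchar(trimws(gpr))))
        return(if (is.list(gpr)) gpr else NULL)
    stopifnot(is.character(gpr), length(gpr) == 1)
    toks <- regmatches(gpr, gregexpr("\\(|\\)|[^()\\s]+", gpr, perl = TRUE))[[1]]
    if (!length(toks)) return(NULL)
    pos <- 1L
    peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
    take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
    parse_primary <- function() {
        t <- peek()
        if (is.na(t)) stop("unexpected end of GPR expression: ", gpr)
        if (t == "(") {
            take()
            e <- parse_or()
            if (!identical(peek(), ")")) stop("unbalanced parentheses in GPR: ", gpr)
            take()
            return(e)
        }
        if (t %in% c(")", "and", "AND", "or", "OR"))
            stop("malformed GPR expression: ", gpr)
        take()
    }
    parse_and <- function() {
        args <- list(parse_primary())
        while (!is.na(peek()) && tolower(peek()) == "and") {
            take()
            args <- c(args, list(parse_primary()))
        }
        if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
    }
    parse_or <- function() {
        args <- list(parse_and())
        while (!is.na(peek()) && tolower(peek()) == "or") {
            take()
            args <- c(args, list(parse_and()))
        }
        if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
    }
    tree <- parse_or()
    if (pos <= length(toks)) stop("trailing tokens in GPR: ", gpr)
    tree
}

#' @rdname gprParse
#' @export
gprGenes <- function(gpr) {
    tree <- gprParse(gpr)
    collect <- function(t) {
        if (is.null(t)) character()
        else if (is.character(t)) t
        else unlist(lapply(t$args, collect), use.names = FALSE)
    }
    unique(collect(tree))
}

#' @rdname gprParse
#' @param removed character vector of knocked-out gene ids (treated as
#'   absent; all other genes are present).
#' @return `gprEvaluate()` returns TRUE when the reaction remains
#'   catalyzable. An empty association evaluates TRUE: reactions without
#'   known genes (spontaneous or orphan) are never disabled by gene
#'   knockouts.
#' @export
gprEvaluate <- function(gpr, removed = character()) {
    tree <- gprParse(gpr)
    if (is.null(tree)) return(TRUE)
    ev <- function(t) {
        if (is.character(t)) return(!(t %in% removed))
        vals <- vapply(t$args, ev, logical(1))
        if (t$op == "and") all(vals) else any(vals)
    }
    ev(tree)
}

#' Genes whose single loss disables every reaction they touch
#'
#' A gene is "paralog-free" when it has no redundant partner anywhere:
#' removing it alone turns every GPR it participates in false. Genes
#' that appear in no GPR are excluded (their loss cannot change the
#' network). This is a structural reading of paralogy (OR-redundancy in
#' the GPRs) and is the gene set eligible for single-knockout screens.
#'
#' @param model a [MetabolicModel-class].
#' @return character vector of gene ids, sorted.
#' @export
paralogFreeGenes <- function(model) {
    rxn <- model@reactions
    touches <- lapply(rxn$gpr, gprGenes)
    all_genes <- sort(unique(unlist(touches)))
    keep <- vapply(all_genes, function(g) {
        idx <- which(vapply(touches, function(gg) g %in% gg, logical(1)))
        all(vapply(idx, function(i) !gprEvaluate(rxn$gpr[i], removed = g),
                   logical(1)))
    }, logical(1))
    all_genes[keep]
}
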