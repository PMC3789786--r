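## SBML input/output. Written against SBML Level 3 + the fbc (flux
## balance constraints) package; the reader additionally accepts Level
## 2 files with note/kinetic-law-encoded bounds and gene associations,
## the dialect of older published models.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sbml_compartment <- function(id, name = id) {
    ext <- grepl("^(e|ext|extern|external|extracellular|out|periplasm)",
                 paste(id, name), ignore.case = TRUE)
    if (ext) "e" else "c"
}

#' Read a constraint-based model from SBML
#'
#' Accepts Level 3 files with fbc bounds, gene products and objectives,
#' and Level 2 files carrying LOWER_BOUND/UPPER_BOUND kinetic-law
#' parameters and "GENE_ASSOCIATION:" notes. Bounds default to
#' (-1000, 1000) for reversible and (0, 1000) for irreversible
#' reactions when no explicit bound is found. Gene-association strings
#' that cannot be parsed are recorded as empty (no association) with a
#' warning. Species marked as boundary condition are dropped from the
#' stoichiometry (their reactions become boundary reactions). A
#' reaction referencing an undeclared species is an error naming the
#' reaction.
#'
#' @param path SBML file.
#' @return a [MetabolicModel-class].
#' @export
readSBML <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    doc <- xml2::read_xml(path)
    ns <- c(s = xml2::xml_ns(doc)[[1]], fbc = FBC_NS)
    model_node <- xml2::xml_find_first(doc, "./s:model", ns)
    if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)

    att <- function(node, name, default = NA_character_) {
        v <- xml2::xml_attr(node, name)
        if (is.na(v)) default else v
    }
    ## compartments
    comp_nodes <- xml2::xml_find_all(model_node,
                                     "./s:listOfCompartments/s:compartment", ns)
    comp_map <- stats::setNames(
        vapply(comp_nodes, function(x)
            .sbml_compartment(att(x, "id"), att(x, "name", "")), ""),
        vapply(comp_nodes, att, "", "id"))

    ## species
    sp <- xml2::xml_find_all(model_node, "./s:listOfSpecies/s:species", ns)
    sp_id <- vapply(sp, att, "", "id")
    boundary <- vapply(sp, function(x)
        identical(att(x, "boundaryCondition"), "true"), logical(1))
    formula <- vapply(sp, function(x)
        xml2::xml_attr(x, "fbc:chemicalFormula", ns), NA_character_)
    charge <- suppressWarnings(as.integer(
        vapply(sp, function(x) xml2::xml_attr(x, "fbc:charge", ns),
               NA_character_)))
    met <- data.frame(id = sp_id,
                      name = vapply(sp, function(x) att(x, "name", ""), ""),
                      compartment = unname(
                          ifelse(vapply(sp, att, "", "compartment") %in%
                                 names(comp_map),
                                 comp_map[vapply(sp, att, "", "compartment")],
                                 "c")),
                      formula = formula, charge = charge,
                      stringsAsFactors = FALSE)
    met$name[!nzchar(met$name)] <- met$id[!nzchar(met$name)]
    keep <- !boundary
    met <- met[keep, , drop = FALSE]
    rownames(met) <- NULL

    ## global flux-bound parameters
    par_nodes <- xml2::xml_find_all(model_node,
                                    "./s:listOfParameters/s:parameter", ns)
    par_val <- stats::setNames(
        suppressWarnings(as.numeric(vapply(par_nodes, att, "", "value"))),
        vapply(par_nodes, att, "", "id"))

    gpr_from_fbc <- function(node) {
        nm <- xml2::xml_name(node)
        if (nm == "geneProductRef") return(xml2::xml_attr(node, "fbc:geneProduct", ns))
        kids <- xml2::xml_children(node)
        parts <- vapply(kids, gpr_from_fbc, "")
        op <- if (nm == "and") " and " else " or "
        paste0("(", paste(parts, collapse = op), ")")
    }

    rx <- xml2::xml_find_all(model_node, "./s:listOfReactions/s:reaction", ns)
    n <- length(rx)
    if (!n) stop("model contains no reactions")
    rid <- vapply(rx, att, "", "id")
    rname <- vapply(rx, function(x) att(x, "name", ""), "")
    rname[!nzchar(rname)] <- rid[!nzchar(rname)]
    lb <- ub <- numeric(n); gpr <- tags <- character(n)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    midx <- stats::setNames(seq_len(nrow(met)), met$id)
    all_sp <- stats::setNames(keep, sp_id)

    for (j in seq_len(n)) {
        node <- rx[[j]]
        rev <- !identical(att(node, "reversible"), "false")
        ## fbc bounds
        lbp <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns)
        ubp <- xml2::xml_attr(node, "fbc:upperFluxBound", ns)
        lbj <- if (!is.na(lbp) && lbp %in% names(par_val)) par_val[[lbp]] else NA
        ubj <- if (!is.na(ubp) && ubp %in% names(par_val)) par_val[[ubp]] else NA
        ## legacy kinetic-law parameters
        if (is.na(lbj) || is.na(ubj)) {
            kl <- xml2::xml_find_all(
                node, ".//s:kineticLaw//s:parameter | .//s:kineticLaw//s:localParameter",
                ns)
            for (p in kl) {
                pid <- toupper(att(p, "id", att(p, "name", "")))
                v <- suppressWarnings(as.numeric(att(p, "value")))
                if (pid == "LOWER_BOUND" && is.na(lbj)) lbj <- v
                if (pid == "UPPER_BOUND" && is.na(ubj)) ubj <- v
            }
        }
        lb[j] <- if (is.na(lbj)) (if (rev) -1000 else 0) else lbj
        ub[j] <- if (is.na(ubj)) 1000 else ubj

        notes <- paste(xml2::xml_text(
            xml2::xml_find_all(node, "./s:notes//*", ns)), collapse = "\n")
        ## gene association: fbc first, then notes
        ga_node <- xml2::xml_find_first(
            node, "./fbc:geneProductAssociation/*", ns)
        ga <- if (!inherits(ga_node, "xml_missing")) gpr_from_fbc(ga_node)
        else {
            mnote <- regmatches(notes,
                                regexpr("GENE_?ASSOCIATION:[^\n]*", notes,
                                        ignore.case = TRUE))
            if (length(mnote)) sub("^[^:]*:\\s*", "", mnote) else ""
        }
        ga <- trimws(ga)
        gpr[j] <- tryCatch({ gprParse(ga); ga }, error = function(e) {
            warning("unparseable gene association for ", rid[j],
                    "; recorded as none", call. = FALSE)
            ""
        })
        tg <- regmatches(notes, regexpr("TAGS:[^\n]*", notes))
        tags[j] <- if (length(tg)) trimws(sub("^TAGS:\\s*", "", tg)) else ""

        nref <- 0L
        for (side in c("listOfReactants", "listOfProducts")) {
            sgn <- if (side == "listOfReactants") -1 else 1
            refs <- xml2::xml_find_all(
                node, paste0("./s:", side, "/s:speciesReference"), ns)
            for (ref in refs) {
                s <- att(ref, "species")
                if (!s %in% names(all_sp))
                    stop("reaction ", rid[j],
                         " references undeclared species: ", s)
                nref <- nref + 1L
                if (!all_sp[[s]]) next   # boundary species: drop
                st <- suppressWarnings(as.numeric(att(ref, "stoichiometry", "1")))
                ii <- c(ii, midx[[s]]); jj <- c(jj, j); xx <- c(xx, sgn * st)
            }
        }
        ## boundary reaction heuristic when tags are absent
        if (!nzchar(tags[j]) &&
            (grepl("^(EX_|R_EX_)", rid[j]) || nref < 2))
            tags[j] <- "exchange"
    }

    S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(nrow(met), n),
                              dimnames = list(met$id, rid))
    ## collapse duplicated species references
    rxn <- data.frame(id = rid, name = rname, lb = lb, ub = ub,
                      gpr = gpr, tags = tags, stringsAsFactors = FALSE)

    ## genes
    gp <- xml2::xml_find_all(model_node,
                             "./fbc:listOfGeneProducts/fbc:geneProduct", ns)
    gene_df <- if (length(gp)) {
        repl <- vapply(gp, function(x) {
            nt <- paste(xml2::xml_text(
                xml2::xml_find_all(x, "./s:notes//*", ns)), collapse = "\n")
            rr <- regmatches(nt, regexpr("REPLICON:[^\n]*", nt))
            if (length(rr)) trimws(sub("^REPLICON:\\s*", "", rr))
            else "chromosome"
        }, "")
        data.frame(id = vapply(gp, function(x) xml2::xml_attr(x, "fbc:id", ns), ""),
                   replicon = repl, stringsAsFactors = FALSE)
    } else data.frame(id = character(), replicon = character(),
                      stringsAsFactors = FALSE)

    ## objective: fbc active objective, else a biomass-named reaction
    obj_ref <- xml2::xml_find_first(
        model_node,
        "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
        ns)
    objective <- if (!inherits(obj_ref, "xml_missing"))
        xml2::xml_attr(obj_ref, "fbc:reaction", ns)
    else {
        cand <- rid[grepl("biomass|growth", paste(rid, rname),
                          ignore.case = TRUE)]
        if (!length(cand)) stop("no objective declared and no biomass-like ",
                                "reaction found")
        cand[1]
    }
    metabolicModel(met, rxn, S, gene_df, objective = objective)
}

#' Write a model as SBML Level 3 with fbc
#'
#' The emitted file round-trips through [readSBML()] to a structurally
#' identical model: ids, names, compartments, formulas, stoichiometry,
#' bounds, gene associations (with replicon notes), tags and the
#' objective are all preserved.
#'
#' @param model a valid [MetabolicModel-class].
#' @param path output file.
#' @export
writeSBML <- function(model, path) {
    validObject(model)
    esc <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        x <- gsub(">", "&gt;", x, fixed = TRUE)
        gsub("\"", "&quot;", x, fixed = TRUE)
    }
    num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con)

    w("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
    w("<sbml xmlns=\"", SBML_NS, "\" level=\"3\" version=\"1\" ",
      "xmlns:fbc=\"", FBC_NS, "\" fbc:required=\"false\">")
    w("  <model id=\"model\" fbc:strict=\"true\">")
    w("    <listOfCompartments>")
    w("      <compartment id=\"c\" name=\"cytosol\" constant=\"true\"/>")
    w("      <compartment id=\"e\" name=\"external\" constant=\"true\"/>")
    w("    </listOfCompartments>")

    w("    <listOfSpecies>")
    met <- model@metabolites
    for (i in seq_len(nrow(met))) {
        extra <- character()
        if (!is.na(met$formula[i]))
            extra <- c(extra, paste0("fbc:chemicalFormula=\"",
                                     esc(met$formula[i]), "\""))
        if (!is.na(met$charge[i]))
            extra <- c(extra, paste0("fbc:charge=\"", met$charge[i], "\""))
        w("      <species id=\"", met$id[i], "\" name=\"", esc(met$name[i]),
          "\" compartment=\"", met$compartment[i],
          "\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
          "constant=\"false\"",
          if (length(extra)) paste0(" ", paste(extra, collapse = " ")) else "",
          "/>")
    }
    w("    </listOfSpecies>")

    ## flux-bound parameters, one per distinct value
    rxn <- model@reactions
    vals <- sort(unique(c(rxn$lb, rxn$ub)))
    pid <- stats::setNames(paste0("fb_", seq_along(vals)),
                           vapply(vals, num, ""))
    w("    <listOfParameters>")
    for (v in vals)
        w("      <parameter id=\"", pid[[num(v)]], "\" value=\"", num(v),
          "\" constant=\"true\"/>")
    w("    </listOfParameters>")

    gpr_xml <- function(tree, indent) {
        pad <- strrep(" ", indent)
        if (is.character(tree))
            return(paste0(pad, "<fbc:geneProductRef fbc:geneProduct=\"",
                          tree, "\"/>"))
        tagn <- paste0("fbc:", tree$op)
        c(paste0(pad, "<", tagn, ">"),
          unlist(lapply(tree$args, gpr_xml, indent + 2)),
          paste0(pad, "</", tagn, ">"))
    }

    w("    <listOfReactions>")
    S <- model@stoichiometry
    for (j in seq_len(nrow(rxn))) {
        w("      <reaction id=\"", rxn$id[j], "\" name=\"", esc(rxn$name[j]),
          "\" reversible=\"", if (rxn$lb[j] < 0) "true" else "false",
          "\" fast=\"false\" fbc:lowerFluxBound=\"", pid[[num(rxn$lb[j])]],
          "\" fbc:upperFluxBound=\"", pid[[num(rxn$ub[j])]], "\">")
        if (nzchar(rxn$tags[j])) {
            w("        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">")
            w("          <p>TAGS: ", esc(rxn$tags[j]), "</p>")
            w("        </body></notes>")
        }
        col <- S[, j]
        nzi <- which(col != 0)
        for (side in c(-1, 1)) {
            sel <- nzi[sign(col[nzi]) == side]
            if (!length(sel)) next
            tagn <- if (side < 0) "listOfReactants" else "listOfProducts"
            w("        <", tagn, ">")
            for (i in sel)
                w("          <speciesReference species=\"", met$id[i],
                  "\" stoichiometry=\"", num(abs(col[i])),
                  "\" constant=\"true\"/>")
            w("        </", tagn, ">")
        }
        if (nzchar(rxn$gpr[j])) {
            w("        <fbc:geneProductAssociation>")
            w(paste(gpr_xml(gprParse(rxn$gpr[j]), 10), collapse = "\n"))
            w("        </fbc:geneProductAssociation>")
        }
        w("      </reaction>")
    }
    w("    </listOfReactions>")

    if (nrow(model@genes)) {
        w("    <fbc:listOfGeneProducts>")
        for (i in seq_len(nrow(model@genes))) {
            g <- model@genes[i, ]
            w("      <fbc:geneProduct fbc:id=\"", g$id, "\" fbc:label=\"",
              g$id, "\">")
            w("        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">")
            w("          <p>REPLICON: ", esc(g$replicon), "</p>")
            w("        </body></notes>")
            w("      </fbc:geneProduct>")
        }
        w("    </fbc:listOfGeneProducts>")
    }

    w("    <fbc:listOfObjectives fbc:activeObjective=\"obj\">")
    w("      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">")
    w("        <fbc:listOfFluxObjectives>")
    w("          <fbc:fluxObjective fbc:reaction=\"", model@objective,
      "\" fbc:coefficient=\"1\"/>")
    w("        </fbc:listOfFluxObjectives>")
    w("      </fbc:objective>")
    w("    </fbc:listOfObjectives>")
    w("  </model>")
    w("</sbml>")
    invisible(path)
}
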