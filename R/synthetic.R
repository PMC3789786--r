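## Seeded generator for a reduced Roseobacter-like core network.
##
## The model is small enough for exhaustive testing yet expresses every
## feature the analyses depend on: carbon-source symporters with a
## sodium/proton antiporter, an Entner-Doudoroff glucose route with the
## phosphofructokinase present but constrained to zero, the literature
## proton-translocating stoichiometries of oxidative phosphorylation, a
## two-reaction aerobic anoxygenic photosystem, capacity-limited
## respiratory denitrification, DMSO reduction, both DMSP degradation
## branches (demethylation via the tetrahydrofolate/serine route,
## cleavage to DMS + acrylate), dual biomass reactions, plasmid-tagged
## genes, a strictly anaerobic corrinoid branch, and a planted dead-end
## pathway. Ground-truth annotations are emitted alongside.

#' Configuration for the core-model generator
#'
#' @param seed integer seed controlling the stochastic knobs (decoy
#'   paralog placement); the network topology itself is deterministic.
#' @param photosystem,denitrification,dmsoReductase,dmspBranches,glyoxylateShunt,deadEndPathway,plasmidTags
#'   feature toggles (all default TRUE).
#' @param dmspExchange must be TRUE when dmspBranches is TRUE.
#' @param nDecoyParalogs number of catabolic genes duplicated into
#'   OR-paralog pairs.
#' @param sinkBound upper bound of the by-product sink reactions,
#'   mmol/(gDW h).
#' @param demethylationCap enzyme-capacity bound on the DMSP
#'   demethylase flux, mmol/(gDW h).
#' @param denitrificationCap capacity bound on the lumped respiratory
#'   nitrate reduction, mmol/(gDW h).
#' @param pfkEnabled when TRUE the phosphofructokinase is generated
#'   with open bounds instead of (0, 0).
#' @export
generatorConfig <- function(seed = 1L, photosystem = TRUE,
                            denitrification = TRUE, dmsoReductase = TRUE,
                            dmspBranches = TRUE, dmspExchange = dmspBranches,
                            glyoxylateShunt = TRUE, deadEndPathway = TRUE,
                            plasmidTags = TRUE, nDecoyParalogs = 2L,
                            sinkBound = 10, demethylationCap = 1,
                            denitrificationCap = 0.05, pfkEnabled = FALSE) {
    if (dmspBranches && !dmspExchange)
        stop("contradictory toggles: DMSP branches require the DMSP exchange")
    structure(list(seed = as.integer(seed), photosystem = photosystem,
                   denitrification = denitrification,
                   dmsoReductase = dmsoReductase,
                   dmspBranches = dmspBranches, dmspExchange = dmspExchange,
                   glyoxylateShunt = glyoxylateShunt,
                   deadEndPathway = deadEndPathway,
                   plasmidTags = plasmidTags,
                   nDecoyParalogs = as.integer(nDecoyParalogs),
                   sinkBound = sinkBound,
                   demethylationCap = demethylationCap,
                   denitrificationCap = denitrificationCap,
                   pfkEnabled = pfkEnabled),
              class = "GeneratorConfig")
}

## metabolite formula registry (cytosolic unless suffixed _e);
## conventions: neutral (protonated) organic acids; nucleotide
## phosphates in their ionized forms; NADH = NAD + H (the hydride);
## cytochromes carry the electron on the iron, element-identical in
## both states; CoA is the pseudo-element R plus its thiol hydrogen.
.core_formulas <- c(
    ## cofactors and inorganics
    atp = "C10H12N5O13P3", adp = "C10H12N5O10P2", pi = "HO4P",
    nad = "C21H26N7O14P2", nadh = "C21H27N7O14P2",
    q = "C49H74O4", qh2 = "C49H76O4", cytox = "Fe", cytred = "Fe",
    coa = "HR", accoa = "C2H3OR",
    h = "H", h2o = "H2O", co2 = "CO2", o2 = "O2", o2rib = "O2",
    nh3 = "H3N", na = "Na", so4 = "H2SO4", h2s = "H2S", no3 = "HNO3",
    n2 = "N2", urea = "CH4N2O", h2o2 = "H2O2", mg = "Mg", co = "Co",
    ## central carbon
    glc = "C6H12O6", g6p = "C6H13O9P", f6p = "C6H13O9P",
    fbp = "C6H14O12P2", gap = "C3H7O6P", dhap = "C3H7O6P",
    pep = "C3H5O6P", pyr = "C3H4O3", oaa = "C4H4O5", mal = "C4H6O5",
    cit = "C6H8O7", icit = "C6H8O7", akg = "C5H6O5", succ = "C4H6O4",
    fum = "C4H4O4", glx = "C2H2O3", formate = "CH2O2",
    ## carbon sources (internal forms)
    hb = "C4H8O3", rlac = "C3H6O3", slac = "C3H6O3", ace = "C2H4O2",
    aglc = "C6H12O6", bglc = "C6H12O6", fru = "C6H12O6",
    xyl = "C5H10O5", rham = "C6H12O5", rbt = "C5H12O5",
    xylt = "C5H12O5", inos = "C6H12O6", etoh = "C2H6O",
    glyc = "C3H8O3", glyclt = "C2H4O3", glu = "C5H9NO4",
    prop = "C3H6O2", dmsp = "C5H10O2S",
    tsa = "C3H4O4", glycerate = "C3H6O4",
    ## sulfur volatiles and DMSP intermediates
    dms = "C2H6S", mt = "CH4S", mmpa = "C4H8O2S", acrylate = "C3H4O2",
    dmso = "C2H6OS",
    ## folate/serine cycle
    thf = "C19H23N7O6", mlthf = "C20H23N7O6", mthf = "C20H25N7O6",
    ser = "C3H7NO3", gly = "C2H5NO2",
    ## biomass monomers and their precursors
    ala = "C3H7NO2", nmp = "C10H14N5O7P", dnmp = "C10H14N5O6P",
    glucan = "C6H10O5", pgU = "C9H15NO6", fa18 = "C18H34O2",
    phbU = "C4H6O2", rhamU = "C6H10O4", rhpre = "C6H13O12P2",
    bchl = "C55H74MgN4O6",
    ## vitamins / soluble pool
    biotin = "C10H16N2O3S", nico = "C6H5NO2", paba = "C7H7NO2",
    thm = "C12H17N4OS", corrin = "C30H40CoN4O5", dmb = "C9H10N2",
    b12 = "C39H50CoN6O5",
    ## folate/thiamin by-products (sunk)
    dhnp = "C9H13N5O4", hmdp = "C7H9N5O2", gcald = "C2H4O2",
    dor = "C5H10O4", cresol = "C7H8O", byprod = "C11H18N8O16P2",
    ## planted dead end
    orphA = "C3H4O3", orphB = "C3H6O3")

## carbon sources: Table-style name -> external metabolite and C count
.carbon_sources <- list(
    "(R)-3-hydroxybutanoate" = list(met = "hb",     C = 4),
    "(R)-lactate"            = list(met = "rlac",   C = 3),
    "(S)-lactate"            = list(met = "slac",   C = 3),
    "2-oxoglutarate"         = list(met = "akg",    C = 5),
    "acetate"                = list(met = "ace",    C = 2),
    "alpha-D-glucose"        = list(met = "aglc",   C = 6),
    "alpha-D-xylopyranose"   = list(met = "xyl",    C = 5),
    "alpha-L-rhamnose"       = list(met = "rham",   C = 6),
    "alpha-maltose"          = list(met = "malt",   C = 12),
    "beta-D-fructofuranose"  = list(met = "fru",    C = 6),
    "beta-D-glucose"         = list(met = "bglc",   C = 6),
    "citrate"                = list(met = "cit",    C = 6),
    "D-ribitol"              = list(met = "rbt",    C = 5),
    "D-xylitol"              = list(met = "xylt",   C = 5),
    "DMSP"                   = list(met = "dmsp",   C = 5),
    "ethanol"                = list(met = "etoh",   C = 2),
    "fumarate"               = list(met = "fum",    C = 4),
    "glycerol"               = list(met = "glyc",   C = 3),
    "glycolate"              = list(met = "glyclt", C = 2),
    "glyoxylate"             = list(met = "glx",    C = 2),
    "L-glutamate"            = list(met = "glu",    C = 5),
    "myo-inositol"           = list(met = "inos",   C = 6),
    "polyhydroxybutyrate"    = list(met = "phbx",   C = 4),
    "propionate"             = list(met = "prop",   C = 3),
    "pyruvate"               = list(met = "pyr",    C = 3),
    "succinate"              = list(met = "succ",   C = 4))

#' Generate the synthetic core model
#'
#' @param config a [generatorConfig()].
#' @return list with elements \code{model} (a
#'   [MetabolicModel-class]) and \code{groundTruth}, a list of planted
#'   facts the pipeline is expected to recover: the paralog-free gene
#'   list, expected blocked reactions, expected knockout phenotypes,
#'   plasmid gene sets, the DMSP branch bookkeeping and the ATP yield
#'   per NADH of the respiratory chain.
#' @export
generateCoreModel <- function(config = generatorConfig()) {
    stopifnot(inherits(config, "GeneratorConfig"))

    mets <- list(); rxns <- list()
    addMet <- function(id, formula, comp = "c", name = id) {
        mets[[id]] <<- list(id = id, name = name, compartment = comp,
                            formula = formula)
    }
    ## internal species
    for (id in names(.core_formulas)) addMet(id, .core_formulas[[id]])
    addMet("unknown", NA_character_, name = "unidentified biomass components")
    ## external pool species
    ext <- c("hb", "rlac", "slac", "akg", "ace", "aglc", "xyl", "rham",
             "fru", "bglc", "cit", "rbt", "xylt", "etoh", "fum", "glyc",
             "glyclt", "glx", "glu", "inos", "prop", "pyr", "succ",
             "dmsp", "o2", "no3", "dmso", "nh3", "urea", "pi", "so4",
             "na", "h", "h2o", "co2", "dms", "mt", "n2", "biotin",
             "nico", "paba", "mg", "co", "o2rib")
    extform <- c(.core_formulas,
                 malt = "C12H22O11", phbx = "C4H6O2", photon = "")
    for (id in ext) addMet(paste0(id, "_e"), extform[[id]], comp = "e")
    addMet("malt_e", "C12H22O11", comp = "e")
    addMet("phbx_e", "C4H6O2", comp = "e")
    addMet("photon_e", "", comp = "e", name = "photon")

    balance_exempt <- c("exchange", "sink", "biomass")
    addRxn <- function(id, st, lb = 0, ub = 1000, gpr = "", tags = "",
                       name = id, exact = FALSE) {
        st <- st[st != 0]
        miss <- setdiff(names(st), names(mets))
        if (length(miss)) stop("reaction ", id, " uses undeclared: ",
                               paste(miss, collapse = ", "))
        exempt <- any(strsplit(tags, ",")[[1]] %in% balance_exempt)
        if (!exempt) {
            net <- numeric(0)
            for (m in names(st)) {
                f <- parseFormula(mets[[m]]$formula)
                if (is.null(f)) stop("reaction ", id,
                                     ": participant without formula: ", m)
                for (el in names(f))
                    net[el] <- (if (el %in% names(net)) net[[el]] else 0) +
                        st[[m]] * f[[el]]
            }
            nonH <- net[setdiff(names(net), "H")]
            if (length(nonH) && any(abs(nonH) > 1e-9))
                stop("reaction ", id, " unbalanced in ",
                     paste(names(nonH)[abs(nonH) > 1e-9], collapse = ","))
            hnet <- if ("H" %in% names(net)) net[["H"]] else 0
            if (abs(hnet) > 1e-9) {
                if (exact) stop("reaction ", id, " not H-balanced as written")
                st["h"] <- (if ("h" %in% names(st)) st[["h"]] else 0) - hnet
                st <- st[st != 0]
            }
        }
        rxns[[id]] <<- list(id = id, name = name, st = st, lb = lb,
                            ub = ub, gpr = gpr, tags = tags)
    }

    ## ---- exchanges ---------------------------------------------------
    EX <- function(met, lb = 0, ub = 1000, tags = "exchange")
        addRxn(paste0("EX_", met), stats::setNames(-1, met), lb, ub,
               tags = tags)
    for (cs in names(.carbon_sources)) {
        m <- .carbon_sources[[cs]]$met
        if (m == "dmsp") {
            if (config$dmspExchange)
                EX("dmsp_e", tags = "exchange,dmsp_exchange")
        } else EX(paste0(m, "_e"))
    }
    EX("o2_e"); EX("no3_e"); EX("dmso_e")
    EX("nh3_e", lb = -1000); EX("urea_e")
    EX("h2o_e", lb = -1000); EX("co2_e", lb = -1000)
    ## the external proton pool exchanges freely (fixed medium pH); the
    ## proton-motive force is still costly because the cytosolic pool
    ## has no exchange and can only be drained by the pumps
    EX("h_e", lb = -1000)
    EX("na_e", lb = -1000); EX("pi_e", lb = -1000); EX("so4_e", lb = -1000)
    EX("mg_e", lb = -1000); EX("co_e", lb = -1000)
    EX("biotin_e", lb = -10); EX("nico_e", lb = -10); EX("paba_e", lb = -10)
    ## dedicated oxygen supply for the corrinoid lower ligand, always open
    EX("o2rib_e", lb = -1000)
    EX("dms_e", tags = "exchange,dms_exchange")
    EX("mt_e"); EX("n2_e")
    if (config$photosystem) EX("photon_e", ub = 0)

    ## ---- transport ---------------------------------------------------
    symport <- function(met, gene, extra_tags = "")
        addRxn(paste0("T_", met),
               stats::setNames(c(-1, -1, 1, 1),
                               c(paste0(met, "_e"), "na_e", met, "na")),
               gpr = gene,
               tags = paste0("transport",
                             if (nzchar(extra_tags)) paste0(",", extra_tags)))
    diffuse <- function(met, lb = -1000, id = paste0("D_", met))
        addRxn(id, stats::setNames(c(-1, 1), c(paste0(met, "_e"), met)),
               lb = lb, tags = "transport")

    sym_genes <- c(hb = "hbcT", rlac = "lctR", slac = "lctS", akg = "kgtP",
                   ace = "actP", aglc = "gluTa", xyl = "xylT",
                   rham = "rhaT", fru = "fruT", bglc = "gluTb",
                   cit = "citT", rbt = "rbtT", xylt = "xytT",
                   inos = "iolT", etoh = "ethT", fum = "dctF",
                   glu = "gltP", prop = "prpT", pyr = "pyrT",
                   succ = "dctA", glyclt = "glcA")
    for (m in names(sym_genes)) symport(m, sym_genes[[m]])
    if (config$dmspExchange) symport("dmsp", "dmspT")
    ## channel-mediated free diffusion (no energy cost): glycerol and
    ## glyoxylate cannot sustain growth if imported at ATP expense
    diffuse("glyc"); diffuse("glx")
    diffuse("o2"); diffuse("co2"); diffuse("nh3"); diffuse("h2o")
    diffuse("dmso"); diffuse("o2rib")
    diffuse("biotin"); diffuse("nico"); diffuse("paba")
    ## volatile products leave by diffusion (export orientation)
    for (vm in c("dms", "mt", "n2"))
        addRxn(paste0("D_", vm),
               stats::setNames(c(-1, 1), c(vm, paste0(vm, "_e"))),
               lb = 0, tags = "transport")
    addRxn("T_urea", c(urea_e = -1, urea = 1), gpr = "urtA", tags = "transport")
    addRxn("T_no3", c(no3_e = -1, no3 = 1), gpr = "narK", tags = "transport")
    addRxn("T_so4", c(so4_e = -1, so4 = 1), gpr = "cysU", tags = "transport")
    addRxn("T_pi", c(pi_e = -1, pi = 1), gpr = "pitA", tags = "transport")
    addRxn("T_mg", c(mg_e = -1, mg = 1), gpr = "mgtA", tags = "transport")
    addRxn("T_co", c(co_e = -1, co = 1), gpr = "corA", tags = "transport")
    ## extracellular hydrolases
    addRxn("MALTASE", c(malt_e = -1, h2o_e = -1, aglc_e = 1, bglc_e = 1),
           gpr = "malZ", tags = "transport")
    addRxn("DEPOLY", c(phbx_e = -1, h2o_e = -1, hb_e = 1),
           gpr = "phaZ", tags = "transport",
           name = "extracellular PHB depolymerase")
    ## sodium/proton antiporter: exchanges two protons for one sodium
    addRxn("NHA", c(na = -1, h_e = -2, na_e = 1, h = 2), gpr = "nhaA",
           tags = "transport,proton_translocating", exact = TRUE,
           name = "Na+/proton antiporter")
    ## flagellar motor proton flux; bounds fixed per physiological state
    addRxn("MOTILITY", c(h_e = -1, h = 1), tags = "motility", exact = TRUE,
           name = "flagellar motor proton flux")

    ## ---- oxidative phosphorylation (literature stoichiometries) ------
    addRxn("NDH", c(nadh = -1, h = -5, q = -1, nad = 1, qh2 = 1, h_e = 4),
           lb = -1000, gpr = "nuoA and nuoB",
           tags = "proton_translocating", exact = TRUE,
           name = "NADH:ubiquinone reductase (H+-translocating)")
    addRxn("CYOO", c(o2 = -1, h = -4, qh2 = -2, h_e = 4, h2o = 2, q = 2),
           gpr = "cyoA", tags = "proton_translocating", exact = TRUE,
           name = "ubiquinol oxidase")
    addRxn("COX", c(h = -8, o2 = -1, cytred = -4, h2o = 2, cytox = 4,
                    h_e = 4),
           gpr = "ctaD and ctaE", tags = "proton_translocating",
           exact = TRUE, name = "cytochrome-c oxidase")
    addRxn("BC1", c(qh2 = -1, cytox = -2, h = -2, q = 1, cytred = 2,
                    h_e = 4),
           gpr = "petA", tags = "proton_translocating", exact = TRUE,
           name = "ubiquinol-cytochrome-c reductase")
    addRxn("ATPS", c(atp = -1, h = -3, h2o = -1, adp = 1, pi = 1, h_e = 4),
           lb = -1000, gpr = "atpA and atpB",
           tags = "proton_translocating", exact = TRUE,
           name = "H+-transporting two-sector ATPase")
    ## non-growth-associated maintenance, always on
    addRxn("NGAM", c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1),
           lb = 3.15, tags = "maintenance", exact = TRUE,
           name = "non-growth-associated ATP maintenance")

    ## ---- photosystem: reaction centre + proton translocation by bc1 --
    if (config$photosystem)
        addRxn("PS_RC", c(photon_e = -2, q = -1, cytred = -2, h = -2,
                          qh2 = 1, cytox = 2),
               gpr = "pufL and pufM", tags = "photosystem", exact = TRUE,
               name = "photosynthetic reaction centre (cyclic)")

    ## ---- alternative electron acceptors -------------------------------
    if (config$denitrification) {
        addRxn("NARL", c(no3 = -2, qh2 = -5, n2 = 1, q = 5, h2o = 6),
               ub = config$denitrificationCap, gpr = "narG",
               tags = "respiratory_nitrate", exact = TRUE,
               name = "respiratory denitrification (lumped)")
    }
    addRxn("NO3ASSIM", c(no3 = -1, nadh = -4, h = -4, nh3 = 1, h2o = 3,
                         nad = 4),
           gpr = "nasA", tags = "assimilatory_nitrate", exact = TRUE,
           name = "assimilatory nitrate reduction")
    if (config$dmsoReductase)
        addRxn("DMSOR", c(dmso = -1, qh2 = -1, dms = 1, h2o = 1, q = 1),
               gpr = "dmsA", tags = "dmso_reductase", exact = TRUE,
               name = "dimethylsulfoxide reductase")

    ## ---- glycolysis / Entner-Doudoroff / gluconeogenesis -------------
    addRxn("ANOM_A", c(aglc = -1, glc = 1), lb = -1000)
    addRxn("ANOM_B", c(bglc = -1, glc = 1), lb = -1000)
    addRxn("GLK", c(glc = -1, atp = -1, g6p = 1, adp = 1), gpr = "glk")
    addRxn("PGI", c(g6p = -1, f6p = 1), lb = -1000, gpr = "pgiA or pgiB")
    addRxn("PFK", c(f6p = -1, atp = -1, fbp = 1, adp = 1),
           lb = 0, ub = if (config$pfkEnabled) 1000 else 0, gpr = "pfkA",
           name = "phosphofructokinase (inactive in vivo)")
    addRxn("ALD", c(fbp = -1, gap = 1, dhap = 1), lb = -1000, gpr = "fbaA")
    addRxn("TPI", c(dhap = -1, gap = 1), lb = -1000, gpr = "tpiA")
    addRxn("ED", c(g6p = -1, nad = -1, pyr = 1, gap = 1, nadh = 1),
           gpr = "edd and eda", name = "Entner-Doudoroff route (lumped)")
    addRxn("GLYL", c(gap = -1, nad = -1, pi = -1, adp = -1, pep = 1,
                     nadh = 1, atp = 1, h2o = 1),
           lb = -1000, gpr = "gapA and pgk",
           name = "lower glycolysis (GAPDH+PGK+ENO, lumped)")
    addRxn("PYK", c(pep = -1, adp = -1, pyr = 1, atp = 1), gpr = "pykA")
    addRxn("PEPCK", c(oaa = -1, atp = -1, pep = 1, adp = 1, co2 = 1),
           gpr = "pckA")
    addRxn("FBPASE", c(fbp = -1, h2o = -1, f6p = 1, pi = 1), gpr = "glpX")
    addRxn("FRK", c(fru = -1, atp = -1, f6p = 1, adp = 1), gpr = "frk")

    ## ---- TCA cycle and anaplerosis ------------------------------------
    addRxn("PDH", c(pyr = -1, coa = -1, nad = -1, accoa = 1, co2 = 1,
                    nadh = 1), gpr = "pdhA and pdhB")
    addRxn("CS", c(accoa = -1, oaa = -1, h2o = -1, cit = 1, coa = 1),
           lb = -1000, gpr = "gltA", name = "citrate synthase")
    addRxn("ACN", c(cit = -1, icit = 1), lb = -1000, gpr = "acnA")
    addRxn("IDH", c(icit = -1, nad = -1, akg = 1, co2 = 1, nadh = 1),
           gpr = "icd")
    addRxn("AKGDH", c(akg = -1, nad = -1, adp = -1, pi = -1, succ = 1,
                      co2 = 1, nadh = 1, atp = 1),
           gpr = "sucA and sucB",
           name = "2-oxoglutarate dehydrogenase + succinyl-CoA synthetase")
    addRxn("SDH", c(succ = -1, q = -1, fum = 1, qh2 = 1), lb = -1000,
           gpr = "sdhA")
    addRxn("FUMASE", c(fum = -1, h2o = -1, mal = 1), lb = -1000,
           gpr = "fumC")
    addRxn("MDH", c(mal = -1, nad = -1, oaa = 1, nadh = 1), lb = -1000,
           gpr = "mdh")
    addRxn("PC", c(pyr = -1, co2 = -1, atp = -1, h2o = -1, oaa = 1,
                   adp = 1, pi = 1), gpr = "pyc",
           name = "pyruvate carboxylase")
    if (config$glyoxylateShunt) {
        addRxn("ICL", c(icit = -1, succ = 1, glx = 1), gpr = "aceA",
               name = "isocitrate lyase")
        addRxn("MS", c(glx = -1, accoa = -1, h2o = -1, mal = 1, coa = 1),
               gpr = "aceB", name = "malate synthase")
    }
    addRxn("ME", c(mal = -1, nad = -1, pyr = 1, co2 = 1, nadh = 1),
           gpr = "maeA", name = "malic enzyme")
    addRxn("PFL", c(pyr = -1, coa = -1, accoa = 1, formate = 1),
           gpr = "pflB", name = "pyruvate formate-lyase")
    addRxn("FDH", c(formate = -1, nad = -1, co2 = 1, nadh = 1),
           gpr = "fdhA")

    ## ---- peripheral catabolism ---------------------------------------
    addRxn("GLYCDH", c(glyclt = -1, nad = -1, glx = 1, nadh = 1),
           gpr = "glcD", name = "glycolate dehydrogenase")
    ## glycerate pathway: net assimilation of C2 units from glyoxylate
    ## (malate synthase alone only supports oxidation, not net growth)
    addRxn("GCL", c(glx = -2, tsa = 1, co2 = 1), gpr = "gcl",
           name = "glyoxylate carboligase")
    addRxn("TSAR", c(tsa = -1, nadh = -1, glycerate = 1, nad = 1),
           gpr = "glxR", name = "tartronate-semialdehyde reductase")
    addRxn("GLYCK", c(glycerate = -1, atp = -1, pep = 1, adp = 1,
                      h2o = 1), gpr = "garK",
           name = "glycerate kinase + phosphoglycerate mutase + enolase")
    addRxn("GLPK", c(glyc = -1, atp = -1, nad = -1, dhap = 1, adp = 1,
                     nadh = 1), gpr = "glpK",
           name = "glycerol kinase + G3P dehydrogenase (lumped)")
    addRxn("GDH", c(glu = -1, h2o = -1, nad = -1, akg = 1, nh3 = 1,
                    nadh = 1), lb = -1000, gpr = "gdhA",
           name = "glutamate dehydrogenase")
    addRxn("LDH_R", c(rlac = -1, nad = -1, pyr = 1, nadh = 1), gpr = "dld")
    addRxn("LDH_S", c(slac = -1, nad = -1, pyr = 1, nadh = 1), gpr = "lldD")
    addRxn("HBDH", c(hb = -1, nad = -1, coa = -2, atp = -1, accoa = 2,
                     nadh = 1, adp = 1, pi = 1), gpr = "bdhA",
           name = "3-hydroxybutanoate catabolism (lumped)")
    addRxn("PROPD", c(prop = -1, h2o = -1, nad = -2, pyr = 1, nadh = 2),
           gpr = "prpD", name = "propionate catabolism (lumped)")
    addRxn("ACS", c(ace = -1, coa = -1, atp = -1, accoa = 1, adp = 1,
                    pi = 1), gpr = "acsA")
    addRxn("ADH", c(etoh = -1, coa = -1, nad = -2, accoa = 1, nadh = 2),
           gpr = "adhE", name = "ethanol catabolism (lumped)")
    ## oxidative funnels to pyruvate: X + r H2O + s NAD -> p pyr + s NADH
    funnel <- function(id, met, gene) {
        f <- parseFormula(.core_formulas[[met]])
        p <- f[["C"]] / 3
        r <- 3 * p - f[["O"]]
        s <- (f[["H"]] + 2 * r - 4 * p) / 2
        addRxn(id, stats::setNames(c(-1, -r, -s, p, s),
                                   c(met, "h2o", "nad", "pyr", "nadh")),
               gpr = gene)
    }
    funnel("XYLD", "xyl", "xylA")
    funnel("RBTD", "rbt", "rbtD")
    funnel("XYLTD", "xylt", "xdhA")
    funnel("INOSD", "inos", "iolG")
    funnel("RHAD", "rham", "rhaD")

    ## ---- DMSP degradation branches ------------------------------------
    if (config$dmspBranches) {
        addRxn("DMDA", c(dmsp = -1, thf = -1, mmpa = 1, mthf = 1),
               ub = config$demethylationCap, gpr = "dmdA",
               tags = "demethylation", name = "DMSP demethylase")
        addRxn("DDD", c(dmsp = -1, dms = 1, acrylate = 1),
               gpr = "dddL or dddD", tags = "cleavage",
               name = "DMSP lyase (cleavage)")
        addRxn("MMPAL", c(mmpa = -1, mt = 1, acrylate = 1), gpr = "dmdB",
               name = "MMPA lyase (methanethiol release)")
        addRxn("ACRD", c(acrylate = -1, h2o = -1, nad = -1, pyr = 1,
                         nadh = 1), gpr = "acuI")
        addRxn("MTHFD", c(mthf = -1, nad = -1, mlthf = 1, nadh = 1),
               gpr = "metF")
    }
    ## serine cycle (also folate-dependent, used by the C1 route)
    addRxn("GHMT", c(gly = -1, mlthf = -1, h2o = -1, ser = 1, thf = 1),
           gpr = "glyA", name = "glycine hydroxymethyltransferase")
    addRxn("SAL", c(ser = -1, pyr = 1, nh3 = 1), gpr = "sdaA",
           name = "L-serine ammonia-lyase")
    addRxn("GLYS", c(co2 = -1, nh3 = -1, mlthf = -1, nadh = -1, gly = 1,
                     thf = 1, nad = 1), gpr = "gcvT",
           name = "glycine synthase (reverse cleavage system)")

    ## ---- nitrogen / sulfur assimilation -------------------------------
    addRxn("UREASE", c(urea = -1, h2o = -1, nh3 = 2, co2 = 1),
           gpr = "ureC")
    addRxn("SO4R", c(so4 = -1, nadh = -4, h2s = 1, h2o = 4, nad = 4),
           gpr = "cysJ", name = "assimilatory sulfate reduction")

    ## ---- oxidative stress ---------------------------------------------
    addRxn("CAT", c(h2o2 = -2, h2o = 2, o2 = 1), gpr = "katA",
           name = "catalase")
    addRxn("PEROX", c(h2o2 = -1, cytred = -2, h = -2, h2o = 2, cytox = 2),
           gpr = "ccpA", name = "cytochrome-c peroxidase")

    ## ---- biomass monomer synthesis ------------------------------------
    addRxn("ALAS", c(pyr = -1, nh3 = -1, nadh = -1, nad = 1, ala = 1,
                     h2o = 1), gpr = "alaD")
    addRxn("NMPS", c(g6p = -1, nh3 = -5, formate = -2, co2 = -2, nmp = 1,
                     h2o = 10), gpr = "purF",
           name = "nucleotide synthesis (lumped)")
    addRxn("DNMPS", c(nmp = -1, nadh = -1, nad = 1, dnmp = 1, h2o = 1),
           gpr = "nrdJ")
    addRxn("GLGS", c(g6p = -1, atp = -1, h2o = -1, glucan = 1, adp = 1,
                     pi = 2), gpr = "glgA")
    addRxn("PGS", c(glucan = -1, ala = -1, atp = -1, pgU = 1, adp = 1,
                    pi = 1), gpr = "murA",
           name = "peptidoglycan unit synthesis (lumped)")
    addRxn("RML1", c(g6p = -1, atp = -1, rhpre = 1, adp = 1),
           gpr = "rmlA", name = "dTDP-rhamnose pathway, activation step")
    addRxn("RML2", c(rhpre = -1, nadh = -1, nad = 1, rhamU = 1, pi = 2),
           gpr = "rmlD", name = "dTDP-rhamnose pathway, reduction step")
    addRxn("FAS", c(accoa = -9, atp = -8, nadh = -16, h2o = -1, fa18 = 1,
                    coa = 9, adp = 8, pi = 8, nad = 16), gpr = "fabF",
           name = "fatty acid (18:1) synthesis, lumped")
    addRxn("PHBS", c(accoa = -2, nadh = -1, phbU = 1, coa = 2, nad = 1),
           gpr = "phaC", name = "PHB monomer synthesis")
    addRxn("BCHLS", c(accoa = -27.5, nh3 = -4, mg = -1, nadh = -50,
                      bchl = 1, coa = 27.5, nad = 50, h2o = 21.5),
           gpr = "bchG", name = "bacteriochlorophyll a synthesis, lumped")
    ## corrinoid branch: the aerobic route is oxygen-dependent (and a
    ## peroxide source); the anaerobic route is oxygen-independent but
    ## carries an extra ATP cost, so aerobic optima prefer the former
    addRxn("CORRIN_AER", c(accoa = -15, nh3 = -4, co = -1, o2 = -1,
                           nadh = -20, corrin = 1, coa = 15, h2o2 = 1,
                           h2o = 10, nad = 20), gpr = "cobG",
           name = "corrin ring synthesis, aerobic route")
    addRxn("CORRIN_ANA", c(accoa = -15, nh3 = -4, co = -1, nadh = -20,
                           atp = -2, corrin = 1, coa = 15, adp = 2,
                           pi = 2, h2o = 8, nad = 20), gpr = "cbiD",
           name = "cobalt-precorrin methylation, anaerobic route")
    addRxn("DMBS", c(nmp = -2, o2rib = -1, dmb = 1, byprod = 1),
           gpr = "bluB",
           name = "5,6-dimethylbenzimidazole synthase (O2-dependent)")
    addRxn("B12S", c(corrin = -1, dmb = -1, b12 = 1), gpr = "cobS")
    addRxn("THMS", c(nmp = -2, pyr = -2, h2s = -1, thm = 1, dor = 1,
                     cresol = 1, co2 = 2, nh3 = 6, pi = 2, h2o = 2),
           gpr = "thiC", name = "thiamin synthesis, lumped")
    ## folate synthesis with its glycolaldehyde by-product
    addRxn("FOL1", c(nmp = -1, h2o = -3, dhnp = 1, formate = 1, pi = 1),
           gpr = "folE")
    addRxn("FOL2", c(dhnp = -1, hmdp = 1, gcald = 1), gpr = "folB",
           name = "dihydroneopterin aldolase")
    addRxn("FOL3", c(hmdp = -1, paba = -1, glu = -1, nadh = -1, thf = 1,
                     h2o = 2, nad = 1), gpr = "folC")

    ## ---- planted dead-end pathway -------------------------------------
    if (config$deadEndPathway) {
        addRxn("DEAD1", c(pyr = -1, orphA = 1), gpr = "yddA")
        addRxn("DEAD2", c(orphA = -1, nadh = -1, nad = 1, orphB = 1),
               gpr = "yddB")
    }

    ## ---- by-product sinks ---------------------------------------------
    SK <- function(met) addRxn(paste0("SK_", met),
                               stats::setNames(-1, met),
                               ub = config$sinkBound, tags = "sink")
    SK("dor"); SK("cresol"); SK("gcald"); SK("byprod")
    ## unidentified biomass components: mass-consistent generic pool
    glucan_mass <- formulaMass(.core_formulas[["glucan"]]) / 1000
    addRxn("UNKSYN", c(glucan = -1 / glucan_mass, unknown = 1),
           tags = "sink", name = "unidentified component pool (1 g/mmol)")

    ## ---- biomass -------------------------------------------------------
    spec <- syntheticBiomassSpec()
    catalog <- c(ala = "ala", dnmp = "dnmp", nmp = "nmp", fa18 = "fa18",
                 phbU = "phbU", rhamU = "rhamU", pgU = "pgU",
                 unknown = "unknown", biotin = "biotin", nico = "nico",
                 paba = "paba", thm = "thm", b12 = "b12", thf = "thf")
    bio <- buildBiomassReactions(spec, catalog,
                                 energyIds = c(atp = "atp", h2o = "h2o",
                                               adp = "adp", pi = "pi",
                                               h = "h"),
                                 bchlId = "bchl")
    for (v in bio)
        addRxn(v$id, v$stoich, lb = 0, ub = 1000, tags = v$tags,
               name = v$name)

    ## ---- decoy paralogs (seeded) ---------------------------------------
    decoy_candidates <- c("XYLD", "RBTD", "XYLTD", "INOSD", "PROPD")
    decoys <- character()
    if (config$nDecoyParalogs > 0) {
        seed_state <- if (exists(".Random.seed", .GlobalEnv))
            get(".Random.seed", .GlobalEnv) else NULL
        on.exit(if (!is.null(seed_state))
            assign(".Random.seed", seed_state, .GlobalEnv), add = TRUE)
        set.seed(config$seed)
        pick <- sample(decoy_candidates,
                       min(config$nDecoyParalogs, length(decoy_candidates)))
        for (rid in sort(pick)) {
            g <- rxns[[rid]]$gpr
            rxns[[rid]]$gpr <- paste0("(", g, " or ", g, "_2)")
            decoys <- c(decoys, g, paste0(g, "_2"))
        }
    }

    ## ---- assemble -------------------------------------------------------
    met_df <- data.frame(id = names(mets),
                         name = vapply(mets, `[[`, "", "name"),
                         compartment = vapply(mets, `[[`, "", "compartment"),
                         formula = vapply(mets, function(m)
                             if (is.na(m$formula)) NA_character_ else m$formula,
                             ""),
                         charge = NA_integer_, stringsAsFactors = FALSE)
    rxn_df <- data.frame(id = names(rxns),
                         name = vapply(rxns, `[[`, "", "name"),
                         lb = vapply(rxns, `[[`, 0, "lb"),
                         ub = vapply(rxns, `[[`, 0, "ub"),
                         gpr = vapply(rxns, `[[`, "", "gpr"),
                         tags = vapply(rxns, `[[`, "", "tags"),
                         stringsAsFactors = FALSE)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (j in seq_along(rxns)) {
        st <- rxns[[j]]$st
        ii <- c(ii, match(names(st), met_df$id))
        jj <- c(jj, rep.int(j, length(st)))
        xx <- c(xx, as.numeric(st))
    }
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(nrow(met_df), nrow(rxn_df)),
                              dimnames = list(met_df$id, rxn_df$id))
    plasmid_86 <- c("rmlA", "rmlD")
    plasmid_153 <- "katA"
    all_genes <- sort(unique(unlist(lapply(rxn_df$gpr, gprGenes))))
    replicon <- rep("chromosome", length(all_genes))
    if (config$plasmidTags) {
        replicon[all_genes %in% plasmid_86] <- "86 kb"
        replicon[all_genes %in% plasmid_153] <- "153 kb"
    }
    gene_df <- data.frame(id = all_genes, replicon = replicon,
                          stringsAsFactors = FALSE)
    model <- metabolicModel(met_df, rxn_df, S, gene_df,
                            objective = "BIOMASS")
    validObject(model)

    or_genes <- c("pgiA", "pgiB", "dddL", "dddD", decoys)
    truth <- list(
        paralogFree = setdiff(all_genes, or_genes),
        orParalogs = sort(intersect(or_genes, all_genes)),
        ## EX_na_e can never carry net flux: sodium enters only by
        ## symport and leaves only by antiport, a closed 1:1 cycle
        blocked = c(if (!config$pfkEnabled) "PFK",
                    if (config$deadEndPathway) c("DEAD1", "DEAD2"),
                    "EX_na_e"),
        phenotypes = c(rmlA = "always_lethal", rmlD = "always_lethal",
                       cbiD = "anaerobic_lethal", pgiB = "no_effect"),
        plasmids = if (config$plasmidTags)
            list("86 kb" = plasmid_86, "153 kb" = plasmid_153) else list(),
        demethylation = list(reaction = "DMDA", cleavage = "DDD",
                             uptake = "T_dmsp", exchange = "EX_dmsp_e",
                             cap = config$demethylationCap),
        atpPerNadh = 2.5,
        biomassMassPerGDW = vapply(bio, `[[`, 0, "massPerGDW"))
    list(model = model, groundTruth = truth)
}

#' Biomass composition spec of the synthetic core model
#'
#' The macromolecule fractions are the experimentally determined ones;
#' each polymer is represented by a single characteristic monomer
#' (alanine for protein, dAMP/AMP for DNA/RNA, the 18:1 fatty acid for
#' lipids, the 3-hydroxybutyryl unit for PHB, a rhamnosyl unit for
#' LPS). The soluble pool is spread over biotin, nicotinate,
#' 4-aminobenzoate, thiamin, cobalamin and tetrahydrofolate with
#' uniform mass shares. Residue masses derive from the formulas; the
#' unidentified fraction is a generic 1 g/mmol pool.
#' @export
syntheticBiomassSpec <- function() {
    sol <- c("biotin", "nico", "paba", "thm", "b12", "thf")
    mono <- list(protein = c(ala = 1), dna = c(dnmp = 1), rna = c(nmp = 1),
                 lipids = c(fa18 = 1), phb = c(phbU = 1),
                 lps = c(rhamU = 1), peptidoglycan = c(pgU = 1),
                 unknown = c(unknown = 1),
                 soluble = stats::setNames(rep(1 / length(sol), length(sol)),
                                           sol))
    monomers <- unique(unlist(lapply(mono, names)))
    masses <- vapply(monomers, function(m) {
        if (m == "unknown") return(1)
        formulaMass(.core_formulas[[m]]) / 1000
    }, 0)
    biomassSpec(monomerFractions = mono, monomerMasses = masses)
}

#' Synthetic genome composition fixture
#'
#' Base counts with an exact GC content (strand-symmetric by
#' construction) and a seeded codon-usage table consistent with that
#' base composition.
#'
#' @param seed integer seed.
#' @param gcContent target G+C fraction.
#' @param genomeLength total bases counted (one strand).
#' @param nCodons total codons in the usage table.
#' @return list with \code{baseCounts} (A, C, G, T), \code{codonUsage}
#'   (named counts over all 64 codons) and \code{gcContent}.
#' @export
generateGenomeComposition <- function(seed = 1L, gcContent = 0.66,
                                      genomeLength = 4e6,
                                      nCodons = 1e5) {
    gcn <- round(genomeLength * gcContent / 2)
    atn <- round(genomeLength * (1 - gcContent) / 2)
    base <- c(A = atn, C = gcn, G = gcn, T = atn)
    seed_state <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(seed_state))
        assign(".Random.seed", seed_state, .GlobalEnv), add = TRUE)
    set.seed(seed)
    codons <- names(GENETIC_CODE_TABLE)
    pbase <- base / sum(base)
    p <- vapply(codons, function(cd) {
        prod(pbase[strsplit(cd, "")[[1]]])
    }, 0)
    p <- p * exp(stats::rnorm(length(p), 0, 0.3))
    usage <- stats::setNames(as.numeric(round(nCodons * p / sum(p))), codons)
    list(baseCounts = base, codonUsage = usage, gcContent = gcContent)
}
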