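# Core stoichiometric network of the Delta-pdc strain and the FBA layer:
# construction (shipped hand-built network, tabular files, SBML L3/FBC),
# kinetic exchange bounds, and lexicographic FBA.

#' Core stoichiometric network
#'
#' @param S stoichiometric matrix (metabolites x reactions, dimnames set).
#' @param lb,ub named flux bounds, mmol gDCW^-1 h^-1.
#' @param biomass_reaction id of the biomass objective reaction.
#' @param exchange_ids named map species -> exchange reaction id; must cover
#'   glc, xyl, o2, actn, bdo, glyc, co2.
#' @param knockouts reaction ids forced to zero flux (bounds (0,0)).
#' @param ngam_id id of the non-growth-associated maintenance reaction
#'   (lower bound zero).
#' @return object of class `core_network`.
#' @export
core_network <- function(S, lb, ub, biomass_reaction, exchange_ids,
                         knockouts = character(), ngam_id = NULL) {
  rxns <- colnames(S)
  stopifnot(!is.null(rxns), !is.null(rownames(S)),
            setequal(names(lb), rxns), setequal(names(ub), rxns))
  need <- c("glc", "xyl", "o2", "actn", "bdo", "glyc", "co2")
  miss <- setdiff(need, names(exchange_ids))
  if (length(miss)) {
    stop_zf(paste("exchange map lacks species:", paste(miss, collapse = ", ")),
            "zf_bad_network")
  }
  if (!all(unlist(exchange_ids) %in% rxns)) {
    stop_zf("exchange_ids reference unknown reactions", "zf_bad_network")
  }
  if (!biomass_reaction %in% rxns) {
    stop_zf("biomass reaction not in network", "zf_bad_network")
  }
  lb <- lb[rxns]; ub <- ub[rxns]
  for (k in knockouts) {
    if (!k %in% rxns) stop_zf(paste("unknown knockout:", k), "zf_bad_network")
    lb[k] <- 0; ub[k] <- 0
  }
  if (!is.null(ngam_id)) lb[ngam_id] <- max(lb[ngam_id], 0)
  structure(list(S = S, lb = lb, ub = ub,
                 metabolites = rownames(S), reactions = rxns,
                 biomass_reaction = biomass_reaction,
                 exchange_ids = exchange_ids, knockouts = knockouts,
                 ngam_id = ngam_id),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  cat(sprintf("Core network: %d reactions, %d metabolites; biomass = %s; knockouts: %s\n",
              length(x$reactions), length(x$metabolites), x$biomass_reaction,
              paste(x$knockouts, collapse = ", ")))
  invisible(x)
}

# biomass precursor drains, mmol per gDCW (carbon content ~40 mmol C/gDCW).
# The ATP coefficient lumps polymerization and growth-associated
# maintenance; it is set high (100 mmol gDCW^-1), consistent with the
# organism's notoriously low, uncoupled growth yield, and calibrated so the
# default batch depletes glucose around 25 h and xylose within the 65 h
# horizon (see the methods vignette).
.BIOMASS_STOICH <- c(g6p = -0.5, r5p = -0.2, e4p = -0.12, g3p = -0.3,
                     pg3 = -3.6, pep = -1.25, pyr = -6.8,
                     atp = -100, adp = 100, pi = 100,
                     nadph = -8, nadp = 8, biomass = 1)

#' Shipped core network of the Delta-pdc strain
#'
#' A hand-built reduction of the strain's core carbon metabolism: glucose
#' and xylose entry, the Entner-Doudoroff route, the pentose phosphate
#' rearrangement, lower glycolysis, the 2,3-BDO branch (als/aldc/bdh with
#' bdh reversible so 2,3-BDO can be re-oxidized when re-uptake is allowed),
#' glycerol formation as an NADPH sink, NADH and NADPH oxidases as
#' electron sinks, a lumped biomass reaction, NGAM, and the knocked-out
#' pyruvate decarboxylase/ethanol branch. It covers the pathway chemistry
#' needed for batch simulation; it is not the 79-reaction supplementary
#' reconstruction and exact reaction/metabolite counts are asserted only
#' against that file.
#'
#' @param po_ratio ATP per NADH oxidized by the respiratory chain
#'   (default 0: respiration serves as an electron sink without energy
#'   coupling, reflecting the organism's uncoupled oxidative metabolism).
#' @return a [core_network()].
#' @export
zm_core_network <- function(po_ratio = 0) {
  rx <- list()
  add <- function(id, eq, lb = 0, ub = 1000) {
    rx[[id]] <<- list(stoich = parse_equation(eq), lb = lb, ub = ub)
  }
  big <- 1000
  # sugar entry and ED route
  add("glk",   "glc + atp -> g6p + adp")
  add("pgi",   "g6p -> f6p", lb = -big)              # reversible
  add("g6pdh", "g6p + nadp -> pg6 + nadph")          # pgl lumped
  add("edd",   "pg6 -> kdpg")
  add("eda",   "kdpg -> pyr + g3p")
  # lower glycolysis
  add("gapdh", "g3p + nad + pi -> dpg13 + nadh", lb = -big)
  add("pgk",   "dpg13 + adp -> pg3 + atp", lb = -big)
  add("pgm",   "pg3 -> pg2", lb = -big)
  add("eno",   "pg2 -> pep", lb = -big)
  add("pyk",   "pep + adp -> pyr + atp")
  # xylose entry and pentose phosphate rearrangement
  add("xylA",  "xyl -> xlu")
  add("xk",    "xlu + atp -> x5p + adp")
  add("rpe",   "x5p -> ru5p", lb = -big)
  add("rpi",   "ru5p -> r5p", lb = -big)
  add("tkt1",  "x5p + r5p -> s7p + g3p", lb = -big)
  add("tal",   "s7p + g3p -> f6p + e4p", lb = -big)
  add("tkt2",  "x5p + e4p -> f6p + g3p", lb = -big)
  # 2,3-BDO branch; bdh reversible allows re-oxidation of the diol
  add("als",   "2 pyr -> alac + co2")
  add("aldc",  "alac -> actn + co2")
  add("bdh",   "actn + nadh -> bdo + nad", lb = -big)
  # glycerol branch: NADPH sink when no external electron acceptor
  add("tpi",   "g3p -> dhap", lb = -big)
  add("gpd",   "dhap + nadph -> glyc3p + nadp")
  add("gpp",   "glyc3p -> glyc + pi")
  # respiration: NADH oxidase (optionally ATP-coupled); NADPH oxidase
  if (po_ratio > 0) {
    add("nox", sprintf("nadh + 0.5 o2 + %g adp + %g pi -> nad + %g atp",
                       po_ratio, po_ratio, po_ratio))
  } else {
    add("nox", "nadh + 0.5 o2 -> nad")
  }
  add("npox",  "nadph + 0.5 o2 -> nadp")
  # knocked-out ethanol branch
  add("pdc",   "pyr -> acald + co2")
  add("adh",   "acald + nadh -> etoh + nad", lb = -big)
  # maintenance and biomass
  add("ngam",  "atp -> adp + pi")
  bm <- .BIOMASS_STOICH
  add("biomass", paste(
    paste(sprintf("%g %s", -bm[bm < 0], names(bm)[bm < 0]), collapse = " + "),
    "->",
    paste(sprintf("%g %s", bm[bm > 0], names(bm)[bm > 0]), collapse = " + ")))
  # exchange reactions (met -> nothing; uptake = negative flux)
  exch <- c(glc = "EX_glc", xyl = "EX_xyl", o2 = "EX_o2", actn = "EX_actn",
            bdo = "EX_bdo", glyc = "EX_glyc", co2 = "EX_co2",
            etoh = "EX_etoh", pi = "EX_pi", biomass = "EX_biomass")
  add("EX_glc",  "glc ->", lb = -big, ub = 0)
  add("EX_xyl",  "xyl ->", lb = -big, ub = 0)
  add("EX_o2",   "o2 ->", lb = -big, ub = 0)
  add("EX_actn", "actn ->", lb = -big)
  add("EX_bdo",  "bdo ->", lb = -big)
  add("EX_glyc", "glyc ->")
  add("EX_co2",  "co2 ->")
  add("EX_etoh", "etoh ->")
  add("EX_pi",   "pi ->", lb = -big)
  add("EX_biomass", "biomass ->")

  mets <- unique(unlist(lapply(rx, function(r) names(r$stoich))))
  S <- matrix(0, length(mets), length(rx),
              dimnames = list(mets, names(rx)))
  for (id in names(rx)) S[names(rx[[id]]$stoich), id] <- rx[[id]]$stoich
  core_network(S,
               lb = vapply(rx, `[[`, numeric(1), "lb"),
               ub = vapply(rx, `[[`, numeric(1), "ub"),
               biomass_reaction = "biomass",
               exchange_ids = as.list(exch),
               knockouts = "pdc", ngam_id = "ngam")
}

#' Build a core network from a model file (or the shipped network)
#'
#' Accepts a tabular reaction file (TSV with columns `id`, `equation`,
#' `lb`, `ub`), an SBML Level 3 file with FBC bounds, or `NULL` for the
#' shipped hand-built network ([zm_core_network()]). Pyruvate decarboxylase
#' is knocked out and NGAM's lower bound cleared to zero wherever those
#' reactions are identifiable.
#'
#' @param model_source path to `.tsv`/`.xml`(SBML), or `NULL`.
#' @param biomass_reaction,ngam_id,pdc_id reaction ids (matched
#'   case-insensitively against common naming if not found verbatim).
#' @param exchange_ids named species -> reaction id map; for file sources
#'   defaults to `EX_<species>` naming.
#' @return a [core_network()].
#' @export
build_core_network <- function(model_source = NULL,
                               biomass_reaction = "biomass",
                               ngam_id = "ngam", pdc_id = "pdc",
                               exchange_ids = NULL) {
  if (is.null(model_source)) return(zm_core_network())
  if (grepl("\\.(xml|sbml)$", model_source, ignore.case = TRUE)) {
    parsed <- read_sbml_network(model_source)
  } else {
    tab <- utils::read.delim(model_source, stringsAsFactors = FALSE)
    need <- c("id", "equation", "lb", "ub")
    if (!all(need %in% names(tab))) {
      stop_zf("tabular model needs columns id, equation, lb, ub",
              "zf_bad_network")
    }
    st <- lapply(tab$equation, parse_equation)
    mets <- unique(unlist(lapply(st, names)))
    S <- matrix(0, length(mets), nrow(tab),
                dimnames = list(mets, tab$id))
    for (j in seq_len(nrow(tab))) S[names(st[[j]]), j] <- st[[j]]
    parsed <- list(S = S,
                   lb = stats::setNames(tab$lb, tab$id),
                   ub = stats::setNames(tab$ub, tab$id))
  }
  rxns <- colnames(parsed$S)
  find_id <- function(id) {
    if (id %in% rxns) return(id)
    hit <- grep(id, rxns, ignore.case = TRUE, value = TRUE)
    if (length(hit)) hit[1] else NA_character_
  }
  bio <- find_id(biomass_reaction)
  if (is.na(bio)) stop_zf("cannot locate a biomass reaction", "zf_bad_network")
  if (is.null(exchange_ids)) {
    sp <- c("glc", "xyl", "o2", "actn", "bdo", "glyc", "co2")
    exchange_ids <- stats::setNames(as.list(paste0("EX_", sp)), sp)
  }
  pdc <- find_id(pdc_id)
  core_network(parsed$S, parsed$lb, parsed$ub, biomass_reaction = bio,
               exchange_ids = exchange_ids,
               knockouts = if (is.na(pdc)) character() else pdc,
               ngam_id = {
                 ng <- find_id(ngam_id)
                 if (is.na(ng)) NULL else ng
               })
}

# minimal SBML Level 3 + FBC reader: species, reactions with stoichiometry,
# flux bounds via fbc:lowerFluxBound/upperFluxBound parameters
read_sbml_network <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )
  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rnodes)) stop_zf("no reactions found in SBML", "zf_bad_network")
  ids <- xml2::xml_attr(rnodes, "id")
  st <- lapply(rnodes, function(rn) {
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(rn, xp)
      sto <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      sto[is.na(sto)] <- 1
      stats::setNames(sign * sto, xml2::xml_attr(nodes, "species"))
    }
    c(refs(".//listOfReactants/speciesReference", -1),
      refs(".//listOfProducts/speciesReference", 1))
  })
  lbp <- xml2::xml_attr(rnodes, "lowerFluxBound")
  ubp <- xml2::xml_attr(rnodes, "upperFluxBound")
  rev <- xml2::xml_attr(rnodes, "reversible") %in% c("true", "1")
  lb <- ifelse(!is.na(lbp), pval[lbp], ifelse(rev, -1000, 0))
  ub <- ifelse(!is.na(ubp), pval[ubp], 1000)
  mets <- unique(unlist(lapply(st, names)))
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (j in seq_along(ids)) if (length(st[[j]])) S[names(st[[j]]), j] <- st[[j]]
  list(S = S, lb = stats::setNames(as.numeric(lb), ids),
       ub = stats::setNames(as.numeric(ub), ids))
}
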