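SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML ids may not contain brackets; the common "[c]" compartment suffix is
# normalized to "_c", and remaining illegal characters to "_"
sanitize_id <- function(x) {
  x <- gsub("\\[([A-Za-z0-9]+)\\]$", "_\\1", x)
  gsub("[^A-Za-z0-9_]", "_", x)
}

num_attr <- function(x) sprintf("%.17g", x)

#' Write a metabolic model to SBML or TSV
#'
#' SBML output is Level 3 Version 1 with the flux-balance-constraints (fbc v2)
#' package carrying bounds, objective and gene products; ids receive the
#' conventional `M_`/`R_`/`G_` prefixes, which [read_model()] strips again, so
#' write-then-read is lossless for models whose ids are already SBML-safe.
#' The TSV dialect writes three tab-separated files (`metabolites.tsv`,
#' `reactions.tsv`, `model.tsv`) into the directory `path`; stoichiometry is
#' encoded as `met:coef` pairs joined by `;`.
#'
#' @param model a `metabolic_model`.
#' @param path output file (sbml) or directory (tsv).
#' @param format `"sbml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("sbml", "tsv")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "tsv") return(write_model_tsv(model, path))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = sanitize_id(model$id),
                             "fbc:strict" = "true")
  loc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cmp in model$compartments)
    xml2::xml_add_child(loc, "compartment", id = cmp, constant = "true")
  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      los, "species", id = paste0("M_", sanitize_id(m$id)), name = m$name,
      compartment = m$compartment, constant = "false",
      boundaryCondition = "false", hasOnlySubstanceUnits = "false")
    if (!is.na(m$formula) && m$formula != "")
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge))
      xml2::xml_set_attr(sp, "fbc:charge", as.character(m$charge))
  }
  lop <- xml2::xml_add_child(mod, "listOfParameters")
  lor <- xml2::xml_add_child(mod, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rid <- sanitize_id(r$id)
    for (side in c("lb", "ub")) {
      val <- if (side == "lb") r$lower_bound else r$upper_bound
      xml2::xml_add_child(lop, "parameter", id = paste0("R_", rid, "_", side),
                          value = num_attr(val), constant = "true")
    }
    rx <- xml2::xml_add_child(
      lor, "reaction", id = paste0("R_", rid), name = r$name,
      reversible = tolower(r$lower_bound < 0), fast = "false",
      "fbc:lowerFluxBound" = paste0("R_", rid, "_lb"),
      "fbc:upperFluxBound" = paste0("R_", rid, "_ub"))
    if (!is.na(r$subsystem) && r$subsystem != "") {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    if (!is.na(r$gene_rule) && r$gene_rule != "") {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      gpr_to_xml(gpa, gpr_parse(r$gene_rule))
    }
    st <- model$stoichiometry[[r$id]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sel <- if (side == "listOfReactants") st < 0 else st > 0
      if (!any(sel)) next
      lst <- xml2::xml_add_child(rx, side)
      for (k in which(sel))
        xml2::xml_add_child(lst, "speciesReference",
                            species = paste0("M_", sanitize_id(names(st)[k])),
                            stoichiometry = num_attr(abs(st[k])),
                            constant = "true")
    }
  }
  loo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", sanitize_id(model$objective_id)),
                      "fbc:coefficient" = "1")
  if (length(model$genes) > 0) {
    log_ <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(log_, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sanitize_id(g)),
                          "fbc:label" = g)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

gpr_to_xml <- function(parent, node) {
  if (is.character(node)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sanitize_id(node)))
  } else {
    grp <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
    for (a in node$args) gpr_to_xml(grp, a)
  }
  invisible(parent)
}

#' Read a metabolic model from SBML or TSV
#'
#' Recovers ids, stoichiometry, flux bounds, GPR rules and the active
#' objective exactly as written by [write_model()]; files from other tools
#' are accepted as long as they use the fbc package for bounds and objective.
#' Malformed content errors with the offending element named.
#'
#' @param path SBML file or TSV directory.
#' @param format `"sbml"` or `"tsv"`.
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("sbml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") return(read_model_tsv(path))
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = SBML_CORE_NS, fbc = SBML_FBC_NS)
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(mod))) stop("SBML parse error: no <model> element")
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)

  comps <- xml2::xml_attr(
    xml2::xml_find_all(mod, ".//s:listOfCompartments/s:compartment", ns), "id")
  sp <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  metabolites <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), "",
                  xml2::xml_attr(sp, "name")),
    formula = ifelse(is.na(xml2::xml_attr(sp, "fbc:chemicalFormula", ns)), "",
                     xml2::xml_attr(sp, "fbc:chemicalFormula", ns)),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp, "fbc:charge", ns))),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)

  params <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  rx <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  stoich <- list()
  reactions <- data.frame(
    id = character(0), name = character(0), lower_bound = numeric(0),
    upper_bound = numeric(0), gene_rule = character(0),
    subsystem = character(0), stringsAsFactors = FALSE)
  for (node in rx) {
    rid <- strip(xml2::xml_attr(node, "id"), "R_")
    lbp <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns)
    ubp <- xml2::xml_attr(node, "fbc:upperFluxBound", ns)
    if (is.na(lbp) || is.na(ubp) || is.na(pval[lbp]) || is.na(pval[ubp]))
      stop("reaction '", rid, "': missing flux bound parameter")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, paste0("./s:", side, "/s:speciesReference"), ns)
      if (length(refs) == 0) next
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      if (side == "listOfReactants") coef <- -coef
      ids <- strip(xml2::xml_attr(refs, "species"), "M_")
      for (k in seq_along(ids))
        st[ids[k]] <- if (ids[k] %in% names(st)) st[[ids[k]]] + coef[k] else coef[k]
    }
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    rule <- if (is.na(xml2::xml_name(gpa))) "" else
      gpr_deparse(gpr_from_xml(xml2::xml_find_first(gpa, "./*", ns), ns))
    note_p <- xml2::xml_find_all(node, "./s:notes//*", ns)
    note_txt <- xml2::xml_text(note_p)
    sub_note <- grep("^SUBSYSTEM: ", note_txt, value = TRUE)
    subsystem <- if (length(sub_note) > 0)
      sub("^SUBSYSTEM: ", "", sub_note[1]) else ""
    reactions <- rbind(reactions, data.frame(
      id = rid, name = ifelse(is.na(xml2::xml_attr(node, "name")), "",
                              xml2::xml_attr(node, "name")),
      lower_bound = pval[[lbp]], upper_bound = pval[[ubp]],
      gene_rule = rule, subsystem = subsystem, stringsAsFactors = FALSE))
    stoich[[rid]] <- st
  }

  fo <- xml2::xml_find_first(
    mod, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (is.na(xml2::xml_name(fo))) stop("SBML parse error: no flux objective")
  objective_id <- strip(xml2::xml_attr(fo, "fbc:reaction", ns), "R_")

  gp <- xml2::xml_find_all(mod, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- xml2::xml_attr(gp, "fbc:label", ns)

  metabolic_model(
    id = xml2::xml_attr(mod, "id"), metabolites = metabolites,
    reactions = reactions, stoichiometry = stoich, genes = genes,
    objective_id = objective_id, compartments = comps)
}

gpr_from_xml <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    sub("^G_", "", xml2::xml_attr(node, "fbc:geneProduct", ns))
  } else if (nm %in% c("and", "or")) {
    kids <- xml2::xml_find_all(node, "./*", ns)
    list(op = nm, args = lapply(kids, gpr_from_xml, ns = ns))
  } else {
    stop("unsupported gene association element: ", nm)
  }
}

# ---- TSV dialect ----------------------------------------------------------

stoich_to_string <- function(st) {
  paste(sprintf("%s:%.17g", names(st), unname(st)), collapse = ";")
}

string_to_stoich <- function(s, reaction_id) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("reaction '", reaction_id, "': malformed stoichiometry string '", s, "'")
  setNames(as.numeric(vapply(kv, `[`, "", 2)), vapply(kv, `[`, "", 1))
}

write_model_tsv <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  hdr <- "# gemfac TSV model dialect; exchange flux sign: negative = uptake"
  met_path <- file.path(path, "metabolites.tsv")
  writeLines(hdr, met_path)
  suppressWarnings(utils::write.table(
    model$metabolites, met_path, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))
  rxn <- model$reactions
  rxn$stoichiometry <- vapply(model$stoichiometry[rxn$id], stoich_to_string, "")
  rxn$lower_bound <- sprintf("%.17g", rxn$lower_bound)
  rxn$upper_bound <- sprintf("%.17g", rxn$upper_bound)
  rxn_path <- file.path(path, "reactions.tsv")
  writeLines(hdr, rxn_path)
  suppressWarnings(utils::write.table(
    rxn, rxn_path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  meta <- data.frame(
    key = c("id", "objective_id", "compartments", "genes"),
    value = c(model$id, model$objective_id,
              paste(model$compartments, collapse = ";"),
              paste(model$genes, collapse = ";")),
    stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(path, "model.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
}

read_model_tsv <- function(path) {
  met <- read_tsv_file(file.path(path, "metabolites.tsv"))
  rxn <- read_tsv_file(file.path(path, "reactions.tsv"))
  meta <- read_tsv_file(file.path(path, "model.tsv"))
  kv <- setNames(meta$value, meta$key)
  met$charge <- suppressWarnings(as.integer(met$charge))
  met$formula[is.na(met$formula)] <- ""
  met$name[is.na(met$name)] <- ""
  stoich <- setNames(
    mapply(string_to_stoich, rxn$stoichiometry, rxn$id, SIMPLIFY = FALSE),
    rxn$id)
  rxn$lower_bound <- as.numeric(rxn$lower_bound)
  rxn$upper_bound <- as.numeric(rxn$upper_bound)
  rxn$gene_rule[is.na(rxn$gene_rule)] <- ""
  rxn$subsystem[is.na(rxn$subsystem)] <- ""
  rxn$name[is.na(rxn$name)] <- ""
  rxn$stoichiometry <- NULL
  genes <- if (is.na(kv[["genes"]]) || kv[["genes"]] == "") character(0) else
    strsplit(kv[["genes"]], ";", fixed = TRUE)[[1]]
  metabolic_model(
    id = kv[["id"]], metabolites = met, reactions = rxn,
    stoichiometry = stoich, genes = genes,
    objective_id = kv[["objective_id"]],
    compartments = strsplit(kv[["compartments"]], ";", fixed = TRUE)[[1]])
}
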