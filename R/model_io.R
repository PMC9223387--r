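## Model I/O: SBML Level 3 (+ fbc version 2) and the community model-JSON
## dialect. Round trips preserve ids, stoichiometry, bounds, GPR strings
## (normalized form), and the objective.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from SBML or JSON
#'
#' @param path file path.
#' @param format "sbml" or "json"; guessed from the file extension when
#'   missing.
#' @return a \code{metabolic_model}.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
    else "sbml"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

#' Write a metabolic model to SBML or JSON
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @param format "sbml" or "json"; guessed from the extension when missing.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
    else "sbml"
  }
  if (format == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

## ---- reaction kind inference -------------------------------------------

#' Classify a reaction by its structural role
#'
#' Exchange reactions touch exactly one extracellular metabolite; boundary
#' reactions on intracellular metabolites are sink/demand reactions;
#' reactions spanning two or more compartments are transports. Biomass and
#' feed pseudo-reactions are recognized by id prefix.
#'
#' @param stoich named numeric stoichiometry.
#' @param met_compartment named character, metabolite id -> compartment id.
#' @param id reaction id.
#' @param extracellular id of the extracellular compartment (default "e").
#' @return one of "internal", "transport", "exchange", "sink_demand",
#'   "biomass", "feed".
#' @export
classify_reaction <- function(stoich, met_compartment, id,
                              extracellular = "e") {
  if (grepl("^(R_)?BIOMASS", id)) return("biomass")
  if (grepl("^(R_)?FEED", id)) return("feed")
  comps <- unique(met_compartment[names(stoich)])
  if (length(stoich) == 1L) {
    return(if (identical(comps, extracellular)) "exchange" else "sink_demand")
  }
  if (length(comps) > 1L) return("transport")
  "internal"
}

## ---- GPR string <-> tree ------------------------------------------------

## grammar: expr := term ("or" term)* ; term := factor ("and" factor)* ;
## factor := gene | "(" expr ")"
parse_gpr <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(NULL)
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    terms <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); terms <- c(terms, list(parse_term()))
    }
    if (length(terms) == 1L) terms[[1]] else list(op = "or", args = terms)
  }
  parse_term <- function() {
    fac <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); fac <- c(fac, list(parse_factor()))
    }
    if (length(fac) == 1L) fac[[1]] else list(op = "and", args = fac)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end in '", s, "'")
    if (t == "(") {
      take(); e <- parse_expr()
      if (!identical(peek(), ")"))
        stop("GPR parse error: missing ')' in '", s, "'")
      take(); e
    } else if (t == ")") {
      stop("GPR parse error: unexpected ')' in '", s, "'")
    } else {
      take(); list(gene = t)
    }
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("GPR parse error: trailing tokens in '", s, "'")
  out
}

deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (!is.null(tree$gene)) return(tree$gene)
  parts <- vapply(tree$args, function(a) {
    s <- deparse_gpr(a)
    if (is.null(a$gene)) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

## normalized GPR string (stable across read/write cycles)
normalize_gpr <- function(s) deparse_gpr(parse_gpr(s))

## ---- JSON dialect -------------------------------------------------------

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  comp <- unlist(doc$compartments)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               molar_mass = if (is.null(m$notes$molar_mass)) NA_real_
               else as.numeric(m$notes$molar_mass))
  }))
  objective <- numeric()
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    gpr <- if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule
    oc <- if (is.null(r$objective_coefficient)) 0 else r$objective_coefficient
    if (oc != 0) objective[[r$id]] <<- oc
    kind <- if (!is.null(r$notes$kind)) r$notes$kind else NA_character_
    list(id = r$id, name = if (is.null(r$name)) r$id else r$name,
         stoichiometry = st, lower_bound = r$lower_bound,
         upper_bound = r$upper_bound, gpr = gpr, kind = kind)
  })
  genes <- vapply(doc$genes, `[[`, "", "id")
  finalize_read(doc$id, comp, mets, rxns, genes, objective)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$molar_mass)) out$notes <- list(molar_mass = m$molar_mass)
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(r$stoichiometry),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = r$gpr,
                notes = list(kind = r$kind))
    if (r$id %in% names(model$objective))
      out$objective_coefficient <- unname(model$objective[[r$id]])
    out
  })
  doc <- list(id = model$id,
              compartments = as.list(model$compartments),
              metabolites = mets,
              reactions = unname(rxns),
              genes = lapply(model$genes, function(g) list(id = g, name = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

## ---- SBML L3 + fbc ------------------------------------------------------

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in ", path, ": ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("SBML parse error: no <model> in ",
                                         path)
  model_id <- xml2::xml_attr(mdl, "id")

  cn <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  comp <- stats::setNames(xml2::xml_attr(cn, "name"), xml2::xml_attr(cn, "id"))
  comp[is.na(comp)] <- names(comp)[is.na(comp)]

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = sub("^M_", "", xml2::xml_attr(sp, "id")),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  sub("^M_", "", xml2::xml_attr(sp, "id")),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
    molar_mass = NA_real_)

  pn <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  params <- stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                            xml2::xml_attr(pn, "id"))

  gp <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                           ns)
  gene_label <- stats::setNames(xml2::xml_attr(gp, "fbc:label", ns = ns),
                                xml2::xml_attr(gp, "fbc:id", ns = ns))
  gene_label[is.na(gene_label)] <-
    sub("^G_", "", names(gene_label)[is.na(gene_label)])

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "fbc:geneProduct", ns = ns)
      return(unname(gene_label[ref]))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, function(k) {
      s <- gpa_to_string(k)
      if (xml2::xml_name(k) %in% c("and", "or")) paste0("(", s, ")") else s
    }, "")
    paste(parts, collapse = paste0(" ", nm, " "))
  }

  rn <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rn, function(node) {
    rid <- sub("^R_", "", xml2::xml_attr(node, "id"))
    get_side <- function(side) {
      refs <- xml2::xml_find_all(
        node, paste0("./s:listOf", side, "/s:speciesReference"), ns)
      stats::setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      sub("^M_", "", xml2::xml_attr(refs, "species")))
    }
    reac <- get_side("Reactants"); prod <- get_side("Products")
    st <- numeric()
    for (k in names(reac)) st[k] <- -reac[[k]]
    for (k in names(prod)) st[k] <- (if (k %in% names(st)) st[[k]] else 0) +
        prod[[k]]
    lb_ref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(params)) params[[lb_ref]]
    else -1e6
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(params)) params[[ub_ref]]
    else 1e6
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      kid <- xml2::xml_children(gpa)
      if (length(kid)) gpa_to_string(kid[[1]]) else ""
    }
    list(id = rid,
         name = if (is.na(xml2::xml_attr(node, "name"))) rid
         else xml2::xml_attr(node, "name"),
         stoichiometry = st, lower_bound = lb, upper_bound = ub,
         gpr = gpr, kind = NA_character_)
  })

  fo <- xml2::xml_find_all(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- stats::setNames(
    as.numeric(xml2::xml_attr(fo, "fbc:coefficient", ns = ns)),
    sub("^R_", "", xml2::xml_attr(fo, "fbc:reaction", ns = ns)))

  finalize_read(model_id, comp, mets, rxns,
                genes = unname(gene_label), objective = objective)
}

finalize_read <- function(model_id, comp, mets, rxns, genes, objective) {
  met_comp <- stats::setNames(mets$compartment, mets$id)
  extra <- if ("e" %in% names(comp)) "e" else names(comp)[1]
  rxns <- lapply(rxns, function(r) {
    if (is.na(r$kind) || is.null(r$kind))
      r$kind <- classify_reaction(r$stoichiometry, met_comp, r$id,
                                  extracellular = extra)
    r$gpr <- normalize_gpr(r$gpr)
    r
  })
  metabolic_model(id = model_id, compartments = comp, metabolites = mets,
                  reactions = rxns, genes = unique(genes),
                  objective = objective)
}

write_model_sbml <- function(model, path) {
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" xmlns:fbc=\"%s\" level=\"3\" ",
                   "version=\"1\" fbc:required=\"false\">"), SBML_NS, FBC_NS),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", esc(model$id)),
    "    <listOfCompartments>")
  for (cid in names(model$compartments))
    lines <- c(lines, sprintf(
      "      <compartment id=\"%s\" name=\"%s\" constant=\"true\"/>",
      cid, esc(model$compartments[[cid]])))
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    frm <- if (is.na(m$formula)) "" else
      sprintf(" fbc:chemicalFormula=\"%s\"", esc(m$formula))
    lines <- c(lines, sprintf(
      paste0("      <species id=\"M_%s\" name=\"%s\" compartment=\"%s\" ",
             "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
             "constant=\"false\"%s/>"),
      m$id, esc(m$name), m$compartment, frm))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  ## one bound parameter per distinct value
  bvals <- sort(unique(c(vapply(model$reactions, `[[`, 0, "lower_bound"),
                         vapply(model$reactions, `[[`, 0, "upper_bound"))))
  bid <- stats::setNames(paste0("bnd_", seq_along(bvals)), num(bvals))
  for (v in bvals)
    lines <- c(lines, sprintf(
      "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
      bid[[num(v)]], num(v)))
  lines <- c(lines, "    </listOfParameters>")
  if (length(model$genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>")
    for (g in model$genes)
      lines <- c(lines, sprintf(
        "      <fbc:geneProduct fbc:id=\"G_%s\" fbc:label=\"%s\"/>",
        g, esc(g)))
    lines <- c(lines, "    </fbc:listOfGeneProducts>")
  }
  gpa_xml <- function(tree, ind) {
    pad <- strrep(" ", ind)
    if (!is.null(tree$gene))
      return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"G_%s\"/>",
                     pad, tree$gene))
    kids <- unlist(lapply(tree$args, gpa_xml, ind = ind + 2))
    c(sprintf("%s<fbc:%s>", pad, tree$op), kids,
      sprintf("%s</fbc:%s>", pad, tree$op))
  }
  lines <- c(lines, "    <listOfReactions>")
  for (r in model$reactions) {
    rev <- if (r$lower_bound < 0) "true" else "false"
    lines <- c(lines, sprintf(
      paste0("      <reaction id=\"R_%s\" name=\"%s\" reversible=\"%s\" ",
             "fast=\"false\" fbc:lowerFluxBound=\"%s\" ",
             "fbc:upperFluxBound=\"%s\">"),
      r$id, esc(r$name), rev, bid[[num(r$lower_bound)]],
      bid[[num(r$upper_bound)]]))
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>")
      for (k in names(reac))
        lines <- c(lines, sprintf(
          paste0("          <speciesReference species=\"M_%s\" ",
                 "stoichiometry=\"%s\" constant=\"true\"/>"),
          k, num(-reac[[k]])))
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>")
      for (k in names(prod))
        lines <- c(lines, sprintf(
          paste0("          <speciesReference species=\"M_%s\" ",
                 "stoichiometry=\"%s\" constant=\"true\"/>"),
          k, num(prod[[k]])))
      lines <- c(lines, "        </listOfProducts>")
    }
    if (nzchar(r$gpr)) {
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 gpa_xml(parse_gpr(r$gpr), 10),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (length(model$objective)) {
    lines <- c(lines,
               "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
               "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
               "        <fbc:listOfFluxObjectives>")
    for (rid in names(model$objective))
      lines <- c(lines, sprintf(
        paste0("          <fbc:fluxObjective fbc:reaction=\"R_%s\" ",
               "fbc:coefficient=\"%s\"/>"),
        rid, num(model$objective[[rid]])))
    lines <- c(lines, "        </fbc:listOfFluxObjectives>",
               "      </fbc:objective>", "    </fbc:listOfObjectives>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
}
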