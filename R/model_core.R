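#' Construct a metabolic model object
#'
#' The central container for constraint-based analysis: compartments,
#' metabolites, reactions with stoichiometry/bounds/GPR, genes, and a linear
#' objective. Fluxes are in mmol gDW^-1 h^-1 unless a reaction is mass-based
#' by construction (biomass and feed pseudo-reactions). Exchange reactions
#' follow the convention negative flux = import, positive flux = export.
#'
#' @param id model identifier.
#' @param compartments named character vector, id -> name.
#' @param metabolites data.frame with columns id, name, compartment and
#'   optionally formula, molar_mass.
#' @param reactions named list; each element a list with fields id, name,
#'   stoichiometry (named numeric, metabolite id -> coefficient),
#'   lower_bound, upper_bound, gpr (character, "" if none), kind (one of
#'   "internal", "transport", "exchange", "sink_demand", "biomass", "feed").
#' @param genes character vector of gene identifiers.
#' @param objective named numeric, reaction id -> weight.
#' @return an object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            genes = character(), objective = numeric()) {
  if (!all(c("id", "name", "compartment") %in% names(metabolites)))
    stop("metabolites must have columns id, name, compartment")
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"molar_mass" %in% names(metabolites)) metabolites$molar_mass <- NA_real_
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(id = id,
                      compartments = compartments,
                      metabolites = metabolites,
                      reactions = reactions,
                      genes = genes,
                      objective = objective),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique metabolite ids, known
#' compartments, stoichiometry keys resolving to metabolites, bound ordering,
#' GPR genes declared, and objective reactions present. Stops with a message
#' naming the offending field.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  if (anyDuplicated(met$id))
    stop("validation: duplicated metabolite id: ",
         met$id[duplicated(met$id)][1])
  bad_comp <- setdiff(unique(met$compartment), names(model$compartments))
  if (length(bad_comp))
    stop("validation: unknown compartment: ", bad_comp[1])
  rxn_ids <- names(model$reactions)
  if (anyDuplicated(rxn_ids))
    stop("validation: duplicated reaction id: ",
         rxn_ids[duplicated(rxn_ids)][1])
  for (r in model$reactions) {
    missing_met <- setdiff(names(r$stoichiometry), met$id)
    if (length(missing_met))
      stop("validation: reaction ", r$id,
           " references missing metabolite: ", missing_met[1])
    if (r$lower_bound > r$upper_bound)
      stop("validation: reaction ", r$id, " has lower_bound > upper_bound")
    if (identical(r$kind, "exchange") && length(r$stoichiometry) != 1L)
      stop("validation: exchange reaction ", r$id,
           " must touch exactly one metabolite")
  }
  gpr_genes <- unique(unlist(lapply(model$reactions,
                                    function(r) gpr_gene_ids(r$gpr))))
  extra <- setdiff(gpr_genes, model$genes)
  if (length(extra))
    stop("validation: GPR gene not declared in genes: ", extra[1])
  bad_obj <- setdiff(names(model$objective), rxn_ids)
  if (length(bad_obj))
    stop("validation: objective reaction not in model: ", bad_obj[1])
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  compartments: ", paste(names(x$compartments), collapse = ", "), "\n",
      sep = "")
  cat("  metabolites:  ", nrow(x$metabolites), "\n", sep = "")
  cat("  reactions:    ", length(x$reactions), "\n", sep = "")
  cat("  genes:        ", length(x$genes), "\n", sep = "")
  if (length(x$objective))
    cat("  objective:    ", paste(names(x$objective), collapse = " + "), "\n",
        sep = "")
  invisible(x)
}

## gene ids appearing in a GPR string
gpr_gene_ids <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(gpr)) return(character())
  toks <- strsplit(gsub("[()]", " ", gpr), "\\s+")[[1]]
  setdiff(toks[nzchar(toks)], c("and", "or", "AND", "OR"))
}

#' Stoichiometric matrix of a model
#'
#' @param model a \code{metabolic_model}.
#' @return dense numeric matrix S (metabolites x reactions) with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Reaction ids of a model, optionally filtered by kind
#' @param model a \code{metabolic_model}.
#' @param kind optional character vector of reaction kinds to keep.
#' @return character vector of reaction ids.
#' @export
reaction_ids <- function(model, kind = NULL) {
  ids <- names(model$reactions)
  if (is.null(kind)) return(ids)
  keep <- vapply(model$reactions, function(r) r$kind %in% kind, TRUE)
  ids[keep]
}

#' Get reaction bounds as a data frame
#' @param model a \code{metabolic_model}.
#' @return data.frame with reaction, lower_bound, upper_bound, kind.
#' @export
reaction_bounds <- function(model) {
  data.frame(reaction = names(model$reactions),
             lower_bound = vapply(model$reactions, `[[`, 0, "lower_bound"),
             upper_bound = vapply(model$reactions, `[[`, 0, "upper_bound"),
             kind = vapply(model$reactions, `[[`, "", "kind"),
             row.names = NULL)
}

#' Set bounds on one or more reactions
#'
#' @param model a \code{metabolic_model}.
#' @param ids reaction ids.
#' @param lower,upper new bounds (recycled); \code{NULL} leaves a bound as is.
#' @return the modified model.
#' @export
set_bounds <- function(model, ids, lower = NULL, upper = NULL) {
  missing_id <- setdiff(ids, names(model$reactions))
  if (length(missing_id)) stop("unknown reaction id: ", missing_id[1])
  if (!is.null(lower)) lower <- rep_len(lower, length(ids))
  if (!is.null(upper)) upper <- rep_len(upper, length(ids))
  for (k in seq_along(ids)) {
    if (!is.null(lower)) model$reactions[[ids[k]]]$lower_bound <- lower[k]
    if (!is.null(upper)) model$reactions[[ids[k]]]$upper_bound <- upper[k]
  }
  model
}

#' Metabolite carried by each exchange reaction
#' @param model a \code{metabolic_model}.
#' @return named character vector, exchange reaction id -> metabolite id.
#' @export
exchange_metabolites <- function(model) {
  ex <- reaction_ids(model, "exchange")
  out <- vapply(ex, function(id) names(model$reactions[[id]]$stoichiometry), "")
  out
}

## strip the compartment suffix ("_c", "_e", ...) from a metabolite id
base_metabolite_id <- function(ids, compartments) {
  pat <- paste0("_(", paste(compartments, collapse = "|"), ")$")
  sub(pat, "", ids)
}

#' Summary statistics for a metabolic model
#'
#' Counts genes, reactions (total, transport, exchange/boundary), metabolites
#' (total, unique after collapsing compartments), per-compartment totals, and
#' node-degree distributions: metabolites per reaction, genes per reaction,
#' reactions per gene and per metabolite.
#'
#' @param model a \code{metabolic_model}.
#' @return list with \code{counts} (data.frame quantity/value),
#'   \code{per_compartment} (data.frame), and \code{degrees} (list of
#'   integer vectors).
#' @export
summarize_model <- function(model) {
  validate_model(model)
  rx <- model$reactions
  kinds <- vapply(rx, `[[`, "", "kind")
  n_transport <- sum(kinds == "transport")
  n_boundary <- sum(kinds %in% c("exchange", "sink_demand"))
  uniq <- unique(base_metabolite_id(model$metabolites$id,
                                    names(model$compartments)))
  counts <- data.frame(
    quantity = c("genes", "reactions", "transport_reactions",
                 "boundary_reactions", "metabolites", "unique_metabolites"),
    value = c(length(model$genes), length(rx), n_transport, n_boundary,
              nrow(model$metabolites), length(uniq)))
  per_comp <- as.data.frame(table(model$metabolites$compartment),
                            stringsAsFactors = FALSE)
  names(per_comp) <- c("compartment", "metabolites")
  mets_per_rxn <- vapply(rx, function(r) length(r$stoichiometry), 0L)
  genes_per_rxn <- vapply(rx, function(r) length(gpr_gene_ids(r$gpr)), 0L)
  rxn_gene <- table(unlist(lapply(rx, function(r) gpr_gene_ids(r$gpr))))
  rxn_met <- table(unlist(lapply(rx, function(r) names(r$stoichiometry))))
  list(counts = counts,
       per_compartment = per_comp,
       degrees = list(metabolites_per_reaction = unname(mets_per_rxn),
                      genes_per_reaction = unname(genes_per_rxn),
                      reactions_per_gene = as.integer(rxn_gene),
                      reactions_per_metabolite = as.integer(rxn_met)))
}

#' Assemble a biomass pseudo-reaction from a composition recipe
#'
#' Builds the biomass reaction from macromolecule mass fractions of 1 gDW and
#' per-macromolecule monomer fractions. The coefficient of monomer m in
#' macromolecule M is fraction(M) x monomer_fraction(m|M) / molar_mass(m),
#' scaled to mmol per gDW, so one unit of biomass flux consumes exactly 1 g
#' of precursors per gDW h. Polymerization energy is charged as
#' \code{energy_cost} mmol ATP hydrolysed (ATP -> ADP + Pi) per gram of
#' protein synthesized.
#'
#' @param recipe list with \code{macromolecule_fractions} (named numeric
#'   summing to 1), \code{monomer_fractions} (named list of named numerics,
#'   each summing to 1, interpreted as mass fractions), and
#'   \code{energy_cost} (mmol ATP per g protein; default 40).
#' @param monomer_masses named numeric, monomer id -> g/mol. Residue masses
#'   (free monomer minus water) should be used for polymerized monomers.
#' @param atp,adp,pi_met metabolite ids used for the energy term.
#' @return a reaction list (see \code{\link{metabolic_model}}) with kind
#'   \code{"biomass"}; stoichiometry keys are monomer ids plus the energy
#'   metabolites.
#' @export
build_biomass_reaction <- function(recipe, monomer_masses,
                                   atp = "atp_c", adp = "adp_c",
                                   pi_met = "pi_c") {
  fr <- recipe$macromolecule_fractions
  if (abs(sum(fr) - 1) > 1e-9)
    stop("macromolecule_fractions must sum to 1")
  stoich <- numeric()
  for (mac in names(fr)) {
    mono <- recipe$monomer_fractions[[mac]]
    if (is.null(mono)) stop("no monomer fractions for macromolecule ", mac)
    if (abs(sum(mono) - 1) > 1e-9)
      stop("monomer fractions for ", mac, " must sum to 1")
    for (m in names(mono)) {
      if (!m %in% names(monomer_masses))
        stop("missing molar mass for monomer ", m)
      coef <- fr[[mac]] * mono[[m]] / monomer_masses[[m]] * 1000
      stoich[m] <- (if (m %in% names(stoich)) stoich[[m]] else 0) - coef
    }
  }
  ## energy: ATP per g protein
  ec <- if (is.null(recipe$energy_cost)) 40 else recipe$energy_cost
  prot <- if ("protein" %in% names(fr)) fr[["protein"]] else 0
  atp_mmol <- ec * prot
  if (atp_mmol > 0) {
    stoich[atp] <- (if (atp %in% names(stoich)) stoich[[atp]] else 0) - atp_mmol
    stoich[adp] <- (if (adp %in% names(stoich)) stoich[[adp]] else 0) + atp_mmol
    stoich[pi_met] <- (if (pi_met %in% names(stoich)) stoich[[pi_met]] else 0) +
      atp_mmol
  }
  list(id = "BIOMASS", name = "biomass assembly",
       stoichiometry = stoich,
       lower_bound = 0, upper_bound = 1e6, gpr = "", kind = "biomass")
}
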