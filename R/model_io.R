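# Model readers and writers: a compact toy-model JSON dialect and SBML
# (Level 3 with the fbc package preferred; Level 2 with notes-based gene
# associations as a fallback). No SBML library is available in this stack,
# so the SBML layer is a purpose-built xml2 reader/writer covering the
# subset of the standard that constraint-based models use.

#' Read a toy metabolic model from JSON
#'
#' The dialect is
#' `{"metabolites": [...], "reactions": [{"id", "stoich": {met: coef}, "lb",
#' "ub", "genes": [...]}, ...], "objective": "rxn_id"}`.
#' Element order in the file is preserved in the model.
#'
#' @param path path to a JSON file.
#' @return A validated [metabolic_model()].
#' @export
read_toy_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$reactions) || length(j$reactions) == 0L) {
    abort("no objective reachable: model has an empty reaction list")
  }
  mets <- vapply(j$metabolites, as.character, character(1))
  rxn_ids <- vapply(j$reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rxn_ids)) {
    abort(paste0("duplicate reaction id: ",
                 paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  }
  S <- matrix(0, length(mets), length(rxn_ids), dimnames = list(mets, rxn_ids))
  lb <- numeric(length(rxn_ids))
  ub <- numeric(length(rxn_ids))
  g2r <- list()
  for (i in seq_along(j$reactions)) {
    r <- j$reactions[[i]]
    st <- r$stoich
    unknown <- setdiff(names(st), mets)
    if (length(unknown) > 0L) {
      abort(paste0("reaction ", r$id, " references unknown metabolite(s): ",
                   paste(unknown, collapse = ", ")))
    }
    for (met in names(st)) S[met, i] <- as.numeric(st[[met]])
    lb[i] <- as.numeric(r$lb)
    ub[i] <- as.numeric(r$ub)
    if (lb[i] > ub[i]) {
      abort(paste0("lower bound exceeds upper bound for reaction(s): ", r$id))
    }
    for (g in r$genes) {
      g <- as.character(g)
      g2r[[g]] <- c(g2r[[g]], rxn_ids[i])
    }
  }
  if (is.null(j$objective)) abort("no objective defined")
  metabolic_model(mets, rxn_ids, S, lb, ub, as.character(j$objective), g2r)
}

#' Write a toy metabolic model as JSON
#'
#' Inverse of [read_toy_model()]; `read_toy_model(write_toy_model(m, p))`
#' reproduces `m` element for element.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_toy_model <- function(model, path) {
  r2g <- gene_reaction_map(model)$reaction_to_genes
  rxns <- lapply(seq_along(model$reactions), function(i) {
    id <- model$reactions[i]
    nz <- which(model$S[, i] != 0)
    st <- as.list(model$S[nz, i])
    names(st) <- model$metabolites[nz]
    list(
      id = id,
      stoich = st,
      lb = model$lb[[i]],
      ub = model$ub[[i]],
      genes = if (is.null(r2g[[id]])) character(0) else sort(r2g[[id]])
    )
  })
  out <- list(
    metabolites = model$metabolites,
    reactions = rxns,
    objective = model$objective
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# --- SBML ------------------------------------------------------------------

sbml_escape <- function(x) gsub("&", "&amp;", x, fixed = TRUE)

#' Write a metabolic model as SBML Level 3 + fbc
#'
#' Emits a minimal, standard-conform SBML document: species in one
#' compartment, reactions with stoichiometry and fbc flux-bound parameters,
#' flattened gene-product associations, and one active maximisation
#' objective on the biomass reaction.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  # one parameter per distinct bound value
  vals <- sort(unique(c(model$lb, model$ub)))
  pid <- setNames(sprintf("fb_%d", seq_along(vals)),
                  format(vals, digits = 15, trim = TRUE))
  pname <- function(v) pid[[format(v, digits = 15, trim = TRUE)]]

  r2g <- gene_reaction_map(model)$reaction_to_genes
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "    <listOfSpecies>"
  )
  for (m in model$metabolites) {
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      sbml_escape(m)))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (v in vals) {
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      pname(v), format(v, digits = 15)))
  }
  lines <- c(lines, "    </listOfParameters>",
             "    <listOfReactions>")
  for (i in seq_along(model$reactions)) {
    id <- model$reactions[i]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      sbml_escape(id), tolower(model$lb[[i]] < 0), pname(model$lb[[i]]),
      pname(model$ub[[i]])))
    genes <- r2g[[id]]
    if (!is.null(genes) && length(genes) > 0L) {
      refs <- sprintf('            <fbc:geneProductRef fbc:geneProduct="%s"/>',
                      sbml_escape(sort(genes)))
      if (length(genes) > 1L) {
        refs <- c("          <fbc:or>", refs, "          </fbc:or>")
      }
      lines <- c(lines, "        <fbc:geneProductAssociation>", refs,
                 "        </fbc:geneProductAssociation>")
    }
    nz <- which(model$S[, i] != 0)
    reac <- nz[model$S[nz, i] < 0]
    prod <- nz[model$S[nz, i] > 0]
    if (length(reac) > 0L) {
      lines <- c(lines, "        <listOfReactants>", sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        sbml_escape(model$metabolites[reac]),
        format(-model$S[reac, i], digits = 15)), "        </listOfReactants>")
    }
    if (length(prod) > 0L) {
      lines <- c(lines, "        <listOfProducts>", sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        sbml_escape(model$metabolites[prod]),
        format(model$S[prod, i], digits = 15)), "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  genes <- model_genes(model)
  if (length(genes) > 0L) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>", sprintf(
      '      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
      sbml_escape(genes), sbml_escape(genes)), "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines,
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    sprintf('        <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            sbml_escape(model$objective)),
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 3 with the fbc package (flux-bound parameters, gene
#' products, an active objective) and Level 2 with legacy conventions
#' (kinetic-law `LOWER_BOUND`/`UPPER_BOUND`/`OBJECTIVE_COEFFICIENT`
#' parameters and `GENE_ASSOCIATION:` notes). Gene associations are
#' flattened to gene-to-reaction membership; boolean AND/OR structure is
#' discarded by design. Species flagged `boundaryCondition="true"` are
#' dropped from the stoichiometry so boundary exchanges keep a single
#' nonzero entry.
#'
#' @param path path to an SBML file.
#' @return A validated [metabolic_model()].
#' @export
read_sbml_model <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # normalise away the fbc prefix (whatever it was declared as) so one set of
  # xpaths serves Level 3 fbc and Level 2 documents alike
  pref <- regmatches(
    txt, regexpr('xmlns:[A-Za-z0-9_]+="http://www\\.sbml\\.org/sbml/[^"]*/fbc/[^"]*"', txt)
  )
  if (length(pref) == 1L) {
    p <- sub('^xmlns:([A-Za-z0-9_]+)=.*$', "\\1", pref)
    txt <- gsub(paste0("<", p, ":"), "<", txt, fixed = TRUE)
    txt <- gsub(paste0("</", p, ":"), "</", txt, fixed = TRUE)
    txt <- gsub(paste0(" ", p, ":"), " ", txt, fixed = TRUE)
  }
  doc <- tryCatch(xml2::read_xml(txt), error = function(e) {
    abort(paste0("SBML parse error in ", path, ": ", conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) abort("SBML parse error: no species found")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_boundary]
  boundary <- sp_id[sp_boundary]

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  # gene product id -> label (Level 3 fbc); labels preferred as gene ids
  gp <- xml2::xml_find_all(doc, ".//listOfGeneProducts/geneProduct")
  gp_attrs <- lapply(gp, xml2::xml_attrs)
  gp_id <- vapply(gp_attrs, function(a) {
    a[[grep("(^|:)id$", names(a))[1]]]
  }, character(1))
  gp_label <- vapply(gp_attrs, function(a) {
    i <- grep("(^|:)label$", names(a))
    if (length(i) > 0L) a[[i[1]]] else NA_character_
  }, character(1))
  gp_map <- setNames(ifelse(is.na(gp_label), gp_id, gp_label), gp_id)

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L) abort("no objective reachable: SBML model has no reactions")
  rxn_ids <- xml2::xml_attr(rx_nodes, "id")
  if (anyDuplicated(rxn_ids)) {
    abort(paste0("SBML parse error: duplicate reaction id ",
                 rxn_ids[duplicated(rxn_ids)][1]))
  }
  S <- matrix(0, length(mets), length(rxn_ids), dimnames = list(mets, rxn_ids))
  lb <- numeric(length(rxn_ids))
  ub <- numeric(length(rxn_ids))
  g2r <- list()
  objective <- NA_character_

  attr_suffix <- function(attrs, suffix) {
    i <- grep(paste0("(^|:)", suffix, "$"), names(attrs))
    if (length(i) > 0L) attrs[[i[1]]] else NA_character_
  }

  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    attrs <- xml2::xml_attrs(node)
    rev_ok <- isTRUE(xml2::xml_attr(node, "reversible") %in% c("true", NA))

    add_stoich <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        if (sp %in% boundary) next
        if (!sp %in% mets) {
          abort(paste0("SBML parse error: reaction ", rxn_ids[i],
                       " references unknown species ", sp))
        }
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        S[sp, i] <<- S[sp, i] + sign * st
      }
    }
    add_stoich("./listOfReactants/speciesReference", -1)
    add_stoich("./listOfProducts/speciesReference", +1)

    # bounds: L3 fbc attributes, else L2 kinetic-law parameters
    lb_ref <- attr_suffix(attrs, "lowerFluxBound")
    ub_ref <- attr_suffix(attrs, "upperFluxBound")
    if (!is.na(lb_ref) && !is.na(ub_ref)) {
      lb[i] <- pval[[lb_ref]]
      ub[i] <- pval[[ub_ref]]
    } else {
      kl <- xml2::xml_find_all(node, ".//kineticLaw//parameter")
      kid <- xml2::xml_attr(kl, "id")
      kv <- as.numeric(xml2::xml_attr(kl, "value"))
      lb[i] <- if ("LOWER_BOUND" %in% kid) kv[kid == "LOWER_BOUND"][1] else
        if (rev_ok) -1000 else 0
      ub[i] <- if ("UPPER_BOUND" %in% kid) kv[kid == "UPPER_BOUND"][1] else 1000
      if ("OBJECTIVE_COEFFICIENT" %in% kid &&
          kv[kid == "OBJECTIVE_COEFFICIENT"][1] != 0) {
        objective <- rxn_ids[i]
      }
    }
    if (lb[i] > ub[i]) {
      abort(paste0("lower bound exceeds upper bound for reaction(s): ", rxn_ids[i]))
    }

    # gene associations: L3 geneProductRef, else L2 GENE_ASSOCIATION note
    refs <- xml2::xml_find_all(node, ".//geneProductAssociation//geneProductRef")
    genes <- character(0)
    if (length(refs) > 0L) {
      gids <- vapply(lapply(refs, xml2::xml_attrs), attr_suffix, character(1),
                     suffix = "geneProduct")
      genes <- unname(gp_map[gids])
      genes[is.na(genes)] <- gids[is.na(genes)]
    } else {
      notes <- xml2::xml_text(xml2::xml_find_all(node, ".//notes"))
      ga <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^<\n]*", notes))
      if (length(ga) > 0L) {
        txt <- sub("GENE_ASSOCIATION:", "", ga[1])
        toks <- strsplit(txt, "[()\\s]+", perl = TRUE)[[1]]
        genes <- setdiff(toks, c("", "and", "or", "AND", "OR"))
      }
    }
    for (g in unique(genes)) g2r[[g]] <- c(g2r[[g]], rxn_ids[i])
  }

  # L3 fbc objective
  fo <- xml2::xml_find_all(doc, ".//listOfObjectives//fluxObjective")
  if (length(fo) > 0L) {
    objective <- attr_suffix(xml2::xml_attrs(fo[[1]]), "reaction")
  }
  if (is.na(objective)) abort("no objective defined")

  g2r <- lapply(g2r, unique)
  metabolic_model(mets, rxn_ids, S, lb, ub, objective, g2r)
}

#' Model summary table
#'
#' One row per reaction with its bounds and associated genes; the standard
#' flat export for inspecting a loaded model.
#'
#' @param model a `metabolic_model`.
#' @return A tibble with columns `reaction`, `lb`, `ub`, `genes`
#'   (comma-separated), `exchange` (logical).
#' @export
model_summary <- function(model) {
  r2g <- gene_reaction_map(model)$reaction_to_genes
  ex <- exchange_reactions(model)
  tibble(
    reaction = model$reactions,
    lb = unname(model$lb),
    ub = unname(model$ub),
    genes = vapply(model$reactions, function(r) {
      paste(sort(r2g[[r]]), collapse = ",")
    }, character(1), USE.NAMES = FALSE),
    exchange = model$reactions %in% ex
  )
}
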