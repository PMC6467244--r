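# Minimal SBML Level 3 Version 2 writer/reader for the competition model.
# The document carries one compartment (the cell, size = vol), the seven
# species as substance amounts, all rate parameters, and one reaction per
# process with a MathML kinetic law written term by term. The layout mirrors
# the deposited reference model (BioModels MODEL1808310001) for the same
# reaction network.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"

mathml <- function(expr) {
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">", expr, "</math>")
}
ci <- function(x) paste0("<ci> ", x, " </ci>")
m_times <- function(...) paste0("<apply><times/>", paste0(..., collapse = ""), "</apply>")
m_divide <- function(a, b) paste0("<apply><divide/>", a, b, "</apply>")

sbml_reactions <- function() {
  # name, reactants, products, kinetic law (MathML body), modifiers
  list(
    list(id = "prot_synthesis", react = character(), prod = "prot_u",
         law = m_times(ci("s_prot"), ci("cell"))),
    list(id = "prot_ydj1_binding", react = c("prot_u", "ydj1_a"), prod = "yp",
         law = m_divide(m_times(ci("kb"), ci("prot_u"), ci("ydj1_a")), ci("cell"))),
    list(id = "prot_release", react = "yp", prod = c("prot_f", "ydj1_a"),
         law = m_times(ci("kr"), ci("yp"))),
    list(id = "prot_u_degradation", react = "prot_u", prod = character(),
         law = m_times(ci("kd_protU"), ci("prot_u"))),
    list(id = "prot_f_degradation", react = "prot_f", prod = character(),
         law = m_times(ci("beta"), ci("kd_protU"), ci("prot_f"))),
    list(id = "yp_client_degradation", react = "yp", prod = "ydj1_a",
         law = m_times(ci("kd_protU"), ci("yp"))),
    list(id = "yp_ydj1_degradation", react = "yp", prod = "prot_u",
         law = m_times(ci("kd_ydj1"), ci("yp"))),
    list(id = "cln3_synthesis", react = character(), prod = "cln3_u",
         law = m_times(ci("s_cln3"), ci("cell"))),
    list(id = "cln3_ydj1_binding", react = c("cln3_u", "ydj1_a"), prod = "yc",
         law = m_divide(m_times(ci("kb"), ci("cln3_u"), ci("ydj1_a")), ci("cell"))),
    list(id = "cln3_release", react = "yc", prod = c("cln3_f", "ydj1_a"),
         law = m_times(ci("kr"), ci("yc"))),
    list(id = "cln3_u_degradation", react = "cln3_u", prod = character(),
         law = m_times(ci("kd_cln3U"), ci("cln3_u"))),
    list(id = "cln3_f_degradation", react = "cln3_f", prod = character(),
         law = m_times(ci("kd_cln3F"), ci("cln3_f"))),
    list(id = "yc_client_degradation", react = "yc", prod = "ydj1_a",
         law = m_times(ci("kd_cln3U"), ci("yc"))),
    list(id = "yc_ydj1_degradation", react = "yc", prod = "cln3_u",
         law = m_times(ci("kd_ydj1"), ci("yc"))),
    list(id = "ydj1_synthesis", react = character(), prod = "ydj1_a",
         law = m_times(ci("s_ydj1"), ci("cell"))),
    list(id = "ydj1_degradation", react = "ydj1_a", prod = character(),
         law = m_times(ci("kd_ydj1"), ci("ydj1_a"))))
}

#' Export the model as SBML Level 3
#'
#' Writes the reaction network (7 species, one reaction per elementary
#' process, term-by-term kinetic laws in MathML) with the parameter values of
#' `params` and, optionally, a state as initial species amounts.
#'
#' @param params A `chap_params` object.
#' @param path Output file path.
#' @param initial Optional named state vector used for `initialAmount`
#'   (default all zero).
#' @return `path`, invisibly.
#' @export
sbml_export <- function(params, path, initial = chap_state()) {
  stopifnot(inherits(params, "chap_params"))
  par_fields <- c("kb", "kr", "s_prot", "s_cln3", "s_ydj1", "kd_protU",
                  "kd_cln3U", "kd_cln3F", "kd_ydj1", "beta", "gamma")
  species <- paste(vapply(state_names(), function(sp) sprintf(
    "<species id=\"%s\" compartment=\"cell\" initialAmount=\"%.17g\" hasOnlySubstanceUnits=\"true\" boundaryCondition=\"false\" constant=\"false\"/>",
    sp, as.numeric(initial[[sp]])), character(1)), collapse = "\n      ")
  pars <- paste(vapply(par_fields, function(f) sprintf(
    "<parameter id=\"%s\" value=\"%.17g\" constant=\"true\"/>",
    f, params[[f]]), character(1)), collapse = "\n      ")
  rxn <- paste(vapply(sbml_reactions(), function(r) {
    refs <- function(tag, sps) {
      if (length(sps) == 0L) return("")
      paste0("<listOf", tag, "s>",
             paste0(sprintf("<speciesReference species=\"%s\" stoichiometry=\"1\" constant=\"true\"/>", sps),
                    collapse = ""),
             "</listOf", tag, "s>")
    }
    paste0("<reaction id=\"", r$id, "\" reversible=\"false\">",
           refs("Reactant", r$react), refs("Product", r$prod),
           "<kineticLaw>", mathml(r$law), "</kineticLaw></reaction>")
  }, character(1)), collapse = "\n      ")
  doc <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="%s" level="3" version="2">
  <model id="chaperone_competition" name="Chaperone competition model of Start">
    <listOfCompartments>
      <compartment id="cell" spatialDimensions="3" size="%.17g" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      %s
    </listOfSpecies>
    <listOfParameters>
      %s
    </listOfParameters>
    <listOfReactions>
      %s
    </listOfReactions>
  </model>
</sbml>', SBML_NS, params$vol, species, pars, rxn)
  # parse before writing so malformed output can never be produced
  xml2::read_xml(doc)
  writeLines(doc, path)
  invisible(path)
}

#' Import a model from SBML
#'
#' Reads an SBML document written by [sbml_export()] (or structurally
#' equivalent), validating that the seven species and all rate parameters are
#' present.
#'
#' @param path SBML file path.
#' @return List with elements `params` (a `chap_params`) and `initial` (a
#'   `chap_state` of the initial amounts).
#' @export
sbml_import <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse error: ", conditionMessage(e), call. = FALSE))
  ns <- c(s = SBML_NS)
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  missing_sp <- setdiff(state_names(), sp_ids)
  if (length(missing_sp))
    stop("SBML parse error: missing species ", paste(missing_sp, collapse = ", "),
         " in listOfSpecies", call. = FALSE)
  amounts <- as.numeric(xml2::xml_attr(sp_nodes, "initialAmount"))
  names(amounts) <- sp_ids
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pv <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  names(pv) <- xml2::xml_attr(par_nodes, "id")
  comp <- xml2::xml_find_first(doc, ".//s:listOfCompartments/s:compartment", ns)
  vol <- as.numeric(xml2::xml_attr(comp, "size"))
  need <- c("kb", "kr", "s_prot", "s_cln3", "s_ydj1", "kd_protU",
            "kd_cln3U", "kd_cln3F", "kd_ydj1", "beta", "gamma")
  if (!all(need %in% names(pv)))
    stop("SBML parse error: missing parameters ",
         paste(setdiff(need, names(pv)), collapse = ", "), call. = FALSE)
  params <- do.call(chap_params, c(as.list(pv[need]), list(vol = vol)))
  initial <- do.call(chap_state, as.list(amounts[state_names()]))
  list(params = params, initial = initial)
}

#' SBML round trip
#'
#' Exports `params`, re-imports the document and returns the imported
#' parameter set after checking that its steady state matches the original
#' within 1e-9 relative.
#'
#' @param params A `chap_params` object.
#' @return The re-imported `chap_params`.
#' @export
sbml_roundtrip <- function(params) {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  sbml_export(params, path)
  back <- sbml_import(path)$params
  s1 <- steady_state(params)
  s2 <- steady_state(back)
  if (max(abs(s1 - s2) / pmax(abs(s1), 1)) > 1e-9)
    stop("round-trip steady state mismatch", call. = FALSE)
  back
}
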