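## Model I/O.
##
## Native format: a TSV reaction table (id, name, equation, lb, ub, gpr,
## kind) plus a JSON sidecar holding metabolites, genes, the objective and
## the genome gene count. An SBML Level 3 subset (species, reactions,
## bounds and charges/formulas via fbc attributes, GPR and reaction kind
## in notes) supports interchange with standard constraint-based tools.

## ---- reaction equation strings -------------------------------------------

## "glc__D_c + atp_c -> g6p_c + adp_c + h_c" -> named signed coefficients
.parseEquation <- function(eq) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>"
           else if (grepl("-->", eq, fixed = TRUE)) "-->"
           else if (grepl("->", eq, fixed = TRUE)) "->"
           else stop("equation lacks an arrow ('->' or '<=>'): ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")  # empty product side
  if (length(sides) != 2L) stop("malformed equation: ", eq)
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    st <- numeric(0)
    for (term in terms) {
      if (!nzchar(term)) stop("malformed equation term in: ", eq)
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1; met <- parts
      } else if (length(parts) == 2L &&
                 grepl("^[0-9.]+$", parts[1])) {
        coef <- as.numeric(parts[1]); met <- parts[2]
      } else stop("malformed equation term '", term, "' in: ", eq)
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) + sign * coef
    }
    st
  }
  left <- parse_side(sides[1], -1)
  right <- parse_side(sides[2], +1)
  st <- left
  for (met in names(right))
    st[met] <- (if (met %in% names(st)) st[[met]] else 0) + right[[met]]
  st <- st[st != 0]
  if (length(st) == 0L) stop("equation cancels to nothing: ", eq)
  st
}

## named signed coefficients -> canonical equation string
.formatEquation <- function(st, reversible = TRUE) {
  fmt <- function(v) {
    coefs <- abs(unname(v))
    paste(ifelse(coefs == 1, names(v),
                 paste(format(coefs, trim = TRUE, digits = 10), names(v))),
          collapse = " + ")
  }
  left <- st[st < 0]; right <- st[st > 0]
  paste(fmt(left), if (reversible) "<=>" else "->", fmt(right))
}

## ---- TSV + JSON native format --------------------------------------------

#' Read or write a metabolic model
#'
#' \code{writeModel}/\code{readModel} round-trip a model through either the
#' native tabular format (a reactions TSV plus a JSON metadata sidecar
#' with the same stem) or an SBML Level 3 subset. The round trip is the
#' identity on ids, stoichiometry, bounds, GPR strings and kinds.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path file path; format is taken from the extension
#'   (\code{.tsv} or \code{.xml}/\code{.sbml}) unless given explicitly.
#' @param format \code{"tsv"} or \code{"sbml"}.
#' @return \code{readModel} returns a validated
#'   \linkS4class{MetabolicModel}; \code{writeModel} returns \code{path}
#'   invisibly.
#' @examples
#' m <- makeNativeModel()
#' tsv <- file.path(tempdir(), "native.tsv")
#' writeModel(m, tsv)
#' m2 <- readModel(tsv)
#' @export
writeModel <- function(model, path, format = c("auto", "tsv", "sbml")) {
  stopifnot(is(model, "MetabolicModel"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path)) "sbml" else "tsv"
  if (format == "sbml") return(.writeSBML(model, path))
  rx <- model@reactions
  tab <- data.frame(
    id = rx$id, name = rx$name,
    equation = vapply(seq_len(nrow(rx)), function(i)
      .formatEquation(rx$stoichiometry[[i]], reversible = rx$lb[i] < 0), ""),
    lb = rx$lb, ub = rx$ub, gpr = rx$gpr, kind = rx$kind)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    metabolites = model@metabolites,
    genes = model@genes,
    objective_reaction = model@objectiveReaction,
    genome_gene_count = model@genomeGeneCount)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.sidecarPath <- function(path) sub("\\.[A-Za-z]+$", ".json", path)

#' @rdname writeModel
#' @export
readModel <- function(path, format = c("auto", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path)) "sbml" else "tsv"
  if (format == "sbml") return(.readSBML(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gpr = "character",
                                          name = "character"))
  need <- c("id", "equation", "lb", "ub", "gpr", "kind")
  if (!all(need %in% names(tab)))
    stop("reaction TSV lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (any(tab$lb > tab$ub))
    stop("invalid bounds (lb > ub) for reaction(s): ",
         paste(tab$id[tab$lb > tab$ub], collapse = ", "))
  tab$gpr[is.na(tab$gpr)] <- ""
  if (!"name" %in% names(tab)) tab$name <- tab$id
  tab$name[is.na(tab$name)] <- ""
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  mets <- as.data.frame(meta$metabolites, stringsAsFactors = FALSE)
  mets$formula[is.na(mets$formula)] <- ""
  mets$charge <- as.integer(mets$charge)
  rx <- data.frame(id = tab$id, name = tab$name, lb = tab$lb, ub = tab$ub,
                   gpr = tab$gpr, kind = tab$kind)
  rx$stoichiometry <- lapply(tab$equation, .parseEquation)
  MetabolicModel(rx, mets,
                 genes = unlist(meta$genes, use.names = FALSE),
                 objectiveReaction = meta$objective_reaction,
                 genomeGeneCount = if (is.null(meta$genome_gene_count))
                   NA_integer_ else meta$genome_gene_count)
}

## ---- SBML Level 3 subset -------------------------------------------------

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

## SBML ids must not start with a digit; metabolite ids like "13dpg_c" get
## an "M_" prefix on export (and symmetric "R_"/"G_" for tidiness)
.sbmlId <- function(x, prefix) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", x))

.writeSBML <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "hyaflux_model",
                             "fbc:strict" = "false")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in c("c", "e"))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  mets <- model@metabolites
  for (i in seq_len(nrow(mets))) {
    attrs <- list(
      id = .sbmlId(mets$id[i], "M_"), name = mets$name[i],
      compartment = if (mets$compartment[i] == "extracellular") "e" else "c",
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false", "fbc:charge" = as.character(mets$charge[i]))
    if (nzchar(mets$formula[i]))
      attrs[["fbc:chemicalFormula"]] <- mets$formula[i]
    do.call(xml2::xml_add_child, c(list(sp, "species"), attrs))
  }
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  rx <- model@reactions
  bvals <- sort(unique(c(rx$lb, rx$ub)))
  bid <- function(v) sprintf("fb_%d", match(v, bvals))
  for (k in seq_along(bvals))
    xml2::xml_add_child(pars, "parameter", id = sprintf("fb_%d", k),
                        value = sprintf("%.17g", bvals[k]),
                        constant = "true")
  rxl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(rx))) {
    rnode <- xml2::xml_add_child(rxl, "reaction",
      id = .sbmlId(rx$id[i], "R_"), name = rx$name[i],
      reversible = if (rx$lb[i] < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = bid(rx$lb[i]),
      "fbc:upperFluxBound" = bid(rx$ub[i]))
    notes <- xml2::xml_add_child(rnode, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("GENE_ASSOCIATION: ", rx$gpr[i]))
    xml2::xml_add_child(body, "p", paste0("KIND: ", rx$kind[i]))
    st <- rx$stoichiometry[[i]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      ln <- xml2::xml_add_child(rnode, "listOfReactants")
      for (k in seq_along(subs))
        xml2::xml_add_child(ln, "speciesReference",
          species = .sbmlId(names(subs)[k], "M_"),
          stoichiometry = format(abs(subs[[k]]), digits = 17),
          constant = "true")
    }
    if (length(prods)) {
      ln <- xml2::xml_add_child(rnode, "listOfProducts")
      for (k in seq_along(prods))
        xml2::xml_add_child(ln, "speciesReference",
          species = .sbmlId(names(prods)[k], "M_"),
          stoichiometry = format(prods[[k]], digits = 17),
          constant = "true")
    }
  }
  gl <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model@genes)
    xml2::xml_add_child(gl, "fbc:geneProduct",
                        "fbc:id" = .sbmlId(g, "G_"), "fbc:label" = g)
  if (!is.na(model@objectiveReaction)) {
    ol <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    on <- xml2::xml_add_child(ol, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    fl <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(fl, "fbc:fluxObjective",
      "fbc:reaction" = .sbmlId(model@objectiveReaction, "R_"),
      "fbc:coefficient" = "1")
  }
  if (!is.na(model@genomeGeneCount)) {
    ann <- xml2::xml_add_child(mdl, "annotation")
    xml2::xml_add_child(ann, "genomeGeneCount",
                        as.character(model@genomeGeneCount))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.readSBML <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  ## fbc-prefixed attributes survive namespace stripping; match by suffix
  attr_by_suffix <- function(node, suffix) {
    a <- xml2::xml_attrs(node)
    hit <- grep(paste0("(^|:)", suffix, "$"), names(a))
    if (length(hit)) a[[hit[1]]] else NA_character_
  }
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    formula = vapply(sp, attr_by_suffix, "", suffix = "chemicalFormula"),
    charge = as.integer(vapply(sp, attr_by_suffix, "", suffix = "charge")),
    compartment = ifelse(xml2::xml_attr(sp, "compartment") == "e",
                         "extracellular", "intracellular"))
  mets$formula[is.na(mets$formula)] <- ""
  mets$charge[is.na(mets$charge)] <- 0L
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                           xml2::xml_attr(pars, "id"))
  rns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rns)
  rx <- data.frame(id = character(n), name = character(n),
                   lb = numeric(n), ub = numeric(n),
                   gpr = character(n), kind = character(n))
  st_list <- vector("list", n)
  for (i in seq_len(n)) {
    node <- rns[[i]]
    rx$id[i] <- strip(xml2::xml_attr(node, "id"), "R_")
    rx$name[i] <- xml2::xml_attr(node, "name")
    rx$lb[i] <- pvals[[attr_by_suffix(node, "lowerFluxBound")]]
    rx$ub[i] <- pvals[[attr_by_suffix(node, "upperFluxBound")]]
    notes <- xml2::xml_text(xml2::xml_find_all(node, "./notes/body/p"))
    gpr <- sub("^GENE_ASSOCIATION: ?", "",
               grep("^GENE_ASSOCIATION:", notes, value = TRUE))
    kind <- sub("^KIND: ?", "", grep("^KIND:", notes, value = TRUE))
    rx$gpr[i] <- if (length(gpr)) gpr else ""
    rx$kind[i] <- if (length(kind)) kind else "internal"
    st <- numeric(0)
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      met <- strip(xml2::xml_attr(ref, "species"), "M_")
      st[met] <- -as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      met <- strip(xml2::xml_attr(ref, "species"), "M_")
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    st_list[[i]] <- st
  }
  if (any(rx$lb > rx$ub))
    stop("invalid bounds (lb > ub) in SBML file for reaction(s): ",
         paste(rx$id[rx$lb > rx$ub], collapse = ", "))
  rx$stoichiometry <- st_list
  gps <- xml2::xml_find_all(doc,
    ".//*[local-name() = 'listOfGeneProducts']/*")
  genes <- vapply(gps, attr_by_suffix, "", suffix = "label")
  obj <- xml2::xml_find_first(doc, ".//*[local-name() = 'fluxObjective']")
  objective <- if (inherits(obj, "xml_missing")) NA_character_
               else strip(attr_by_suffix(obj, "reaction"), "R_")
  ggc <- xml2::xml_find_first(doc, ".//annotation/genomeGeneCount")
  ggc <- if (inherits(ggc, "xml_missing")) NA_integer_
         else as.integer(xml2::xml_text(ggc))
  MetabolicModel(rx, mets, genes = genes, objectiveReaction = objective,
                 genomeGeneCount = ggc)
}
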