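## Biomass and HA pseudo-reaction construction.
##
## Macromolecular composition is derived from sequence data (genome for
## DNA, coding sequences or codon usage for protein), converted into
## mmol-per-gram-biomass precursor coefficients, and combined with
## growth-associated maintenance ATP into one biomass pseudo-reaction.

## monomer id -> formula of the charged species (pH 7); used for
## molecular weights when no model is attached
.MONOMER_FORMULAS <- c(
  damp = "C10H12N5O6P", dtmp = "C10H13N2O8P", dcmp = "C9H12N3O7P",
  dgmp = "C10H12N5O7P",
  amp = "C10H12N5O7P", ump = "C9H11N2O9P", cmp = "C9H12N3O8P",
  gmp = "C10H12N5O8P",
  ala__L = "C3H7NO2", arg__L = "C6H15N4O2", asn__L = "C4H8N2O3",
  asp__L = "C4H6NO4", cys__L = "C3H7NO2S", gln__L = "C5H10N2O3",
  glu__L = "C5H8NO4", gly = "C2H5NO2", his__L = "C6H9N3O2",
  ile__L = "C6H13NO2", leu__L = "C6H13NO2", lys__L = "C6H15N2O2",
  met__L = "C5H11NO2S", phe__L = "C9H11NO2", pro__L = "C5H9NO2",
  ser__L = "C3H7NO3", thr__L = "C4H9NO3", trp__L = "C11H12N2O2",
  tyr__L = "C9H11NO3", val__L = "C5H11NO2")

.AA_ONE_TO_ID <- c(A = "ala__L", R = "arg__L", N = "asn__L",
  D = "asp__L", C = "cys__L", Q = "gln__L", E = "glu__L", G = "gly",
  H = "his__L", I = "ile__L", L = "leu__L", K = "lys__L",
  M = "met__L", F = "phe__L", P = "pro__L", S = "ser__L",
  T = "thr__L", W = "trp__L", Y = "tyr__L", V = "val__L")

.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  Biostrings::DNAStringSet(x)
}

#' DNA composition from a genome sequence
#'
#' Deoxyribonucleotide molar fractions under double-strand counting:
#' chromosomal DNA is base-paired, so each A on the given strand implies
#' a T opposite it and the dAMP and dTMP fractions are both
#' (A + T) / 2N (likewise dCMP/dGMP with C + G). Ambiguous bases are
#' skipped and their count reported in the \code{"ambiguous"} attribute.
#'
#' @param genome a \code{DNAStringSet}, a FASTA path, or a character
#'   vector of sequences.
#' @return named numeric (dAMP, dTMP, dCMP, dGMP) summing to 1.
#' @examples
#' dnaComposition("ATGC")  # 0.25 each
#' @export
dnaComposition <- function(genome) {
  seqs <- .asDNAStringSet(genome)
  if (length(seqs) == 0L || sum(Biostrings::width(seqs)) == 0L)
    stop("empty genome sequence")
  counts <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  total <- sum(counts)
  if (total == 0L) stop("genome contains no unambiguous A/C/G/T bases")
  ambiguous <- sum(Biostrings::width(seqs)) - total
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  out <- c(dAMP = at, dTMP = at, dCMP = gc, dGMP = gc) / (2 * total)
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Protein composition from coding sequences or codon usage
#'
#' Translates coding sequences with the standard genetic code (terminal
#' stops dropped; a CDS with an internal stop is skipped with a warning)
#' or expands a codon-usage count table, then normalizes amino-acid
#' counts to molar fractions.
#'
#' @param cds a \code{DNAStringSet}, FASTA path or character vector of
#'   CDS sequences (lengths divisible by 3), or a named numeric vector
#'   of codon counts (names are codons of the standard code).
#' @return named numeric of amino-acid molar fractions (ids like
#'   \code{"ala__L"}), summing to 1.
#' @examples
#' proteinComposition("ATGAAA")            # Met 0.5, Lys 0.5
#' proteinComposition(c(GGT = 10))         # Gly 1.0
#' @export
proteinComposition <- function(cds) {
  if (is.numeric(cds)) {
    codons <- names(cds)
    if (is.null(codons)) stop("codon table must be named by codon")
    codons <- toupper(gsub("U", "T", codons))
    known <- codons %in% names(Biostrings::GENETIC_CODE)
    if (!all(known))
      stop("invalid codon(s): ", paste(codons[!known], collapse = ", "))
    aa <- Biostrings::GENETIC_CODE[codons]
    keep <- aa != "*"
    counts <- tapply(as.numeric(cds)[keep], aa[keep], sum)
  } else {
    seqs <- .asDNAStringSet(cds)
    if (length(seqs) == 0L) stop("no coding sequences given")
    if (any(Biostrings::width(seqs) %% 3L != 0L))
      stop("CDS length not divisible by 3")
    counts <- numeric(0)
    for (i in seq_along(seqs)) {
      aa <- as.character(Biostrings::translate(
        seqs[[i]], if.fuzzy.codon = "error"))
      aa <- sub("\\*$", "", aa)              # trailing stop
      if (grepl("\\*", aa)) {
        warning("internal stop codon in CDS ", i, "; sequence skipped")
        next
      }
      tab <- table(strsplit(aa, "")[[1]])
      for (a in names(tab))
        counts[a] <- (if (a %in% names(counts)) counts[a] else 0) + tab[[a]]
    }
    if (length(counts) == 0L) stop("no translatable coding sequences")
  }
  ids <- .AA_ONE_TO_ID[names(counts)]
  if (anyNA(ids))
    stop("untranslatable residues: ",
         paste(names(counts)[is.na(ids)], collapse = ", "))
  out <- as.numeric(counts) / sum(counts)
  names(out) <- ids
  out[order(names(out))]
}

#' Maintenance energy parameters
#'
#' @param gam growth-associated maintenance: mmol ATP hydrolyzed per
#'   gram biomass formed (default 39.4).
#' @param ngam non-growth-associated maintenance: mmol ATP/gDCW/h spent
#'   on cellular upkeep independent of growth.
#' @return a \code{maintenanceParameters} list.
#' @export
maintenanceParameters <- function(gam = 39.4, ngam = 1.0) {
  stopifnot(gam >= 0, ngam >= 0)
  structure(list(gam = gam, ngam = ngam), class = "maintenanceParameters")
}

#' Assemble a biomass pseudo-reaction
#'
#' Converts macromolecule compositions into precursor coefficients
#' (mmol per gram biomass: mass fraction times molar fraction divided by
#' the composition-weighted monomer weight) and appends the GAM term
#' (ATP + H2O -> ADP + Pi + H, \code{gam} mmol per gram). Monomer ids
#' get a \code{"_c"} compartment suffix. The polymerization water is
#' folded into the monomer coefficients, so the consumed mass equals the
#' mass-fraction total exactly; [biomassMassCheck()] verifies this.
#'
#' @param composition list with molar-fraction vectors \code{dna},
#'   \code{rna}, \code{protein} (any subset, each summing to 1) and a
#'   named \code{massFractions} vector (g per gDCW, same names, summing
#'   to at most 1).
#' @param maintenance a [maintenanceParameters()].
#' @param extras optional named numeric of additional precursor
#'   coefficients (mmol/gDCW, metabolite ids with compartment suffix),
#'   e.g. a fixed lipid/cell-wall template.
#' @return list with \code{reaction} (a one-row reaction data.frame,
#'   kind \code{"pseudo"}), \code{coefficients} (mmol/gDCW by metabolite)
#'   and \code{massCheck} (grams of biomass per unit flux).
#' @examples
#' comp <- list(protein = proteinComposition(c(ATGAAA = "ATGAAA")),
#'              massFractions = c(protein = 1))
#' bm <- assembleBiomass(comp, maintenanceParameters())
#' bm$massCheck  # ~1 g
#' @export
assembleBiomass <- function(composition, maintenance = maintenanceParameters(),
                            extras = NULL) {
  stopifnot(inherits(maintenance, "maintenanceParameters"))
  mf <- composition$massFractions
  if (is.null(mf)) stop("composition$massFractions is required")
  if (sum(mf) > 1 + 1e-9) stop("mass fractions sum above 1 g/gDCW")
  id_map <- c(dAMP = "damp", dTMP = "dtmp", dCMP = "dcmp", dGMP = "dgmp",
              AMP = "amp", UMP = "ump", CMP = "cmp", GMP = "gmp")
  coefs <- numeric(0)
  for (macro in intersect(names(mf), c("dna", "rna", "protein"))) {
    frac <- composition[[macro]]
    if (is.null(frac)) stop("no composition given for '", macro, "'")
    if (abs(sum(frac) - 1) > 1e-9)
      stop("molar fractions of '", macro, "' do not sum to 1")
    ids <- ifelse(names(frac) %in% names(id_map),
                  id_map[names(frac)], names(frac))
    mw <- vapply(.MONOMER_FORMULAS[ids], .formulaWeight, 0)
    if (anyNA(mw)) stop("unknown monomer in '", macro, "' composition")
    mean_mw <- sum(frac * mw)                   # g/mol of the average monomer
    add <- 1000 * mf[[macro]] * frac / mean_mw  # mmol per g biomass
    met <- paste0(ids, "_c")
    for (k in seq_along(add))
      coefs[met[k]] <- (if (met[k] %in% names(coefs))
        coefs[[met[k]]] else 0) + add[[k]]
  }
  for (nm in names(extras))
    coefs[nm] <- (if (nm %in% names(coefs)) coefs[[nm]] else 0) + extras[[nm]]
  grams <- sum(coefs * vapply(
    sub("_c$", "", names(coefs)),
    function(b) .formulaWeight(.MONOMER_FORMULAS[[b]]), 0)) / 1000
  gam <- maintenance$gam
  st <- -coefs
  st["atp_c"] <- (if ("atp_c" %in% names(st)) st[["atp_c"]] else 0) - gam
  st["h2o_c"] <- (if ("h2o_c" %in% names(st)) st[["h2o_c"]] else 0) - gam
  st["adp_c"] <- gam; st["pi_c"] <- gam; st["h_c"] <- gam
  rx <- data.frame(id = "BIOMASS", name = "biomass pseudo-reaction",
                   lb = 0, ub = 1000, gpr = "", kind = "pseudo")
  rx$stoichiometry <- list(st)
  list(reaction = rx, coefficients = coefs, massCheck = grams)
}

#' Mass accounting for a biomass reaction
#'
#' Sums consumed minus produced mass (coefficients times molecular
#' weight) over a biomass pseudo-reaction using the metabolite formulas
#' of the model it is attached to; a sound biomass reaction drains close
#' to 1 g per unit flux.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param reaction biomass reaction id (default the model objective).
#' @return net grams drained per unit flux.
#' @export
biomassMassCheck <- function(model, reaction = objectiveReaction(model)) {
  i <- .rxnIndex(model, reaction)
  st <- model@reactions$stoichiometry[[i]]
  mets <- model@metabolites
  mw <- vapply(names(st), function(m) {
    f <- mets$formula[match(m, mets$id)]
    if (is.na(f) || !nzchar(f)) stop("metabolite '", m, "' has no formula")
    .formulaWeight(f)
  }, 0)
  -sum(st * mw) / 1000
}

#' Non-growth-associated maintenance reaction
#'
#' @param maintenance a [maintenanceParameters()]; the reaction's lower
#'   bound is pinned to \code{ngam} so the hydrolysis flux is always
#'   spent.
#' @return one-row reaction data.frame (ATPM: ATP + H2O -> ADP + Pi + H).
#' @export
ngamReaction <- function(maintenance = maintenanceParameters()) {
  rx <- data.frame(id = "ATPM", name = "ATP maintenance (NGAM)",
                   lb = maintenance$ngam, ub = 1000, gpr = "",
                   kind = "pseudo")
  rx$stoichiometry <- list(c(atp_c = -1, h2o_c = -1, adp_c = 1,
                             pi_c = 1, h_c = 1))
  rx
}

#' NGAM from a maintenance-state glucose uptake
#'
#' Under zero growth the entire catabolic ATP production serves upkeep,
#' so NGAM equals the measured maintenance glucose consumption times the
#' network's ATP yield per glucose.
#'
#' @param qGlcMaintenance glucose uptake at zero growth (mmol/gDCW/h).
#' @param atpYield mol ATP per mol glucose, e.g. [atpYieldPerGlucose()].
#' @return NGAM in mmol ATP/gDCW/h.
#' @examples
#' ngamFromMaintenanceUptake(1, 2)  # 2
#' @export
ngamFromMaintenanceUptake <- function(qGlcMaintenance, atpYield) {
  stopifnot(qGlcMaintenance >= 0, atpYield >= 0)
  qGlcMaintenance * atpYield
}

## the elementary HA route shared by both toy models: reaction id ->
## flux per disaccharide unit (two glucoses enter by hexokinase)
.HA_ROUTE <- c(GLCt = 2, GLK = 2, PGI = 1, PGMT = 1, GALU = 1,
               UDPGD = 1, GLMS = 1, GNA1 = 1, PGAMT = 1, GLMU = 1,
               HAS = 1)

#' HA pathway: condensation, exchange and cost report
#'
#' Locates the hyaluronan synthase (condensation) and HA exchange
#' reactions and prices one disaccharide unit by summing the
#' stoichiometry of the elementary route from glucose: net ATP
#' equivalents (direct ATP, plus one per UTP consumed since UTP is
#' regenerated from UDP by nucleoside-diphosphate kinase at one ATP,
#' plus one per glutamine consumed for its regeneration by glutamine
#' synthetase), acetyl-CoA, and NAD reduced. On the default pathway this
#' is 5 ATP equivalents, 1 acetyl-CoA and 2 NAD per disaccharide.
#'
#' @param model a \linkS4class{MetabolicModel} containing the HA branch.
#' @param haMetabolite intracellular HA unit id (default \code{"ha_c"}).
#' @param route named multiplicity vector of the elementary route
#'   (reaction id -> flux per disaccharide); the default matches the
#'   synthetic models' hexokinase entry route.
#' @return list with \code{condensation} and \code{exchange} (reaction
#'   ids), \code{cost} (list: \code{atp_equivalents}, \code{acetyl_coa},
#'   \code{nad}) and \code{net} (net route stoichiometry).
#' @examples
#' haPathway(makeNativeModel())$cost
#' @export
haPathway <- function(model, haMetabolite = "ha_c", route = .HA_ROUTE) {
  rx <- model@reactions
  produces_ha <- vapply(rx$stoichiometry, function(st)
    haMetabolite %in% names(st) && st[[haMetabolite]] > 0, TRUE)
  cond <- rx$id[produces_ha & rx$kind != "exchange"]
  if (length(cond) != 1L)
    stop("expected exactly one condensation reaction producing '",
         haMetabolite, "'")
  ext <- sub("_c$", "_e", haMetabolite)
  is_ex <- vapply(seq_len(nrow(rx)), function(i)
    rx$kind[i] == "exchange" && ext %in% names(rx$stoichiometry[[i]]), TRUE)
  if (!any(is_ex)) stop("no HA exchange reaction found")
  missing_rxn <- setdiff(names(route), rx$id)
  if (length(missing_rxn))
    stop("HA precursor branch incomplete; missing reaction(s): ",
         paste(missing_rxn, collapse = ", "))
  net <- numeric(0)
  for (r in names(route)) {
    st <- rx$stoichiometry[[match(r, rx$id)]] * route[[r]]
    for (m in names(st))
      net[m] <- (if (m %in% names(net)) net[[m]] else 0) + st[[m]]
  }
  if (abs((if ("ha_c" %in% names(net)) net[["ha_c"]] else 0) - 1) > 1e-9)
    stop("elementary route does not produce exactly one HA unit")
  consumed <- function(m) if (m %in% names(net)) max(-net[[m]], 0) else 0
  cost <- list(
    atp_equivalents = consumed("atp_c") + consumed("utp_c") +
      consumed("gln__L_c"),
    acetyl_coa = consumed("accoa_c"),
    nad = consumed("nad_c"))
  list(condensation = cond, exchange = rx$id[is_ex][1], cost = cost,
       net = net)
}
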