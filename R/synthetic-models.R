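## Deterministic generators for the toy model pair.
##
## Two small but biochemically honest networks stand in for the native
## and recombinant HA producers:
##
## * the NATIVE model is a fastidious fermentative lactic bacterium:
##   glucose enters by PTS or permease+hexokinase, EMP glycolysis runs to
##   pyruvate, redox is balanced by lactate (or, aerobically, an
##   NADH oxidase), the TCA cycle is truncated after isocitrate
##   dehydrogenase (its only NADPH source), there is no oxidative
##   pentose-phosphate branch, several amino acids are strictly
##   auxotrophic, pyrimidines come de novo or from uracil salvage, and an
##   HA branch condenses UDP-glucuronate with UDP-N-acetylglucosamine;
##
## * the RECOMBINANT model is a prototrophic respiring host: oxidative
##   PPP (glucose-6-phosphate dehydrogenase analog "zwf_syn"), complete
##   Krebs cycle, electron transport chain with proton-coupled ATP
##   synthase, NADPH-dependent amino-acid biosynthesis, and the same HA
##   branch as a heterologous module.
##
## Every metabolite carries a real elemental formula and pH-7 charge, so
## balance checks are meaningful; internal and transport reactions are
## exactly element- and charge-balanced. Lumped biosynthesis reactions
## (lysine, valine, de novo UMP) conserve atoms of the true pathways.
## The HA disaccharide unit is modeled as the C14H20NO11(-) anion.
##
## Amino-acid uptake caps in the default medium emulate transport-limited
## supplementation: a biosynthesis knockout then survives on imports but
## grows slower, which is what makes precursor-drain deletions divert
## carbon into the HA branch under MOMA.

#' Parameters for the synthetic toy models
#'
#' @param seed integer recorded with the model; generation is fully
#'   deterministic, so identical parameters always yield byte-identical
#'   serialized models.
#' @param glucoseUptake glucose uptake bound, mmol/gDCW/h (defaults:
#'   18.56 native, 4.67 recombinant).
#' @param includeOxidativePpp include the oxidative pentose-phosphate
#'   branch (recombinant trait).
#' @param includeFullTca complete Krebs cycle plus electron transport
#'   chain (recombinant trait).
#' @param includeNox NADH oxidase for the fermentative oxygen response
#'   (native trait).
#' @param nAuxotrophies number (0-5) of strictly auxotrophic amino acids
#'   built into the native biomass (His, Trp, Phe, Tyr, Cys in order).
#' @param ngam non-growth-associated maintenance, mmol ATP/gDCW/h.
#' @param gam growth-associated maintenance, mmol ATP/gDCW.
#' @return a \code{syntheticModelParams} list.
#' @export
syntheticModelParams <- function(seed = 1L, glucoseUptake = 18.56,
                                 includeOxidativePpp = FALSE,
                                 includeFullTca = FALSE,
                                 includeNox = TRUE,
                                 nAuxotrophies = 5L,
                                 ngam = 1.0, gam = 39.4) {
  stopifnot(glucoseUptake > 0, nAuxotrophies >= 0L, nAuxotrophies <= 5L,
            ngam >= 0, gam >= 0)
  structure(list(seed = as.integer(seed), glucoseUptake = glucoseUptake,
                 includeOxidativePpp = includeOxidativePpp,
                 includeFullTca = includeFullTca,
                 includeNox = includeNox,
                 nAuxotrophies = as.integer(nAuxotrophies),
                 ngam = ngam, gam = gam),
            class = "syntheticModelParams")
}

## amino-acid uptake caps of the default medium (mmol/gDCW/h); aspartate
## supply is scarcest, which makes knockouts upstream of the aspartate
## family (ppc analog) collapse growth hardest
.AA_CAP <- 0.30
.ASP_CAP <- 0.05
.URA_CAP <- 0.27

.AUX_AA <- c("his__L", "trp__L", "phe__L", "tyr__L", "cys__L")
.SYN_AA <- c("ala__L", "asp__L", "asn__L", "glu__L", "gln__L",
             "lys__L", "val__L")

## master metabolite table; id base -> name, formula, charge
.MET_DATA <- local({
  d <- rbind(
    c("glc__D", "D-glucose", "C6H12O6", 0),
    c("fru", "D-fructose", "C6H12O6", 0),
    c("gal", "D-galactose", "C6H12O6", 0),
    c("sucr", "sucrose", "C12H22O11", 0),
    c("malt", "maltose", "C12H22O11", 0),
    c("lcts", "lactose", "C12H22O11", 0),
    c("g6p", "D-glucose 6-phosphate", "C6H11O9P", -2),
    c("f6p", "D-fructose 6-phosphate", "C6H11O9P", -2),
    c("fdp", "D-fructose 1,6-bisphosphate", "C6H10O12P2", -4),
    c("dhap", "dihydroxyacetone phosphate", "C3H5O6P", -2),
    c("g3p", "glyceraldehyde 3-phosphate", "C3H5O6P", -2),
    c("13dpg", "1,3-bisphosphoglycerate", "C3H4O10P2", -4),
    c("3pg", "3-phosphoglycerate", "C3H4O7P", -3),
    c("2pg", "2-phosphoglycerate", "C3H4O7P", -3),
    c("pep", "phosphoenolpyruvate", "C3H2O6P", -3),
    c("pyr", "pyruvate", "C3H3O3", -1),
    c("lac__D", "D-lactate", "C3H5O3", -1),
    c("for", "formate", "CHO2", -1),
    c("etoh", "ethanol", "C2H6O", 0),
    c("accoa", "acetyl-CoA", "C23H34N7O17P3S", -4),
    c("coa", "coenzyme A", "C21H32N7O16P3S", -4),
    c("actp", "acetyl phosphate", "C2H3O5P", -2),
    c("ac", "acetate", "C2H3O2", -1),
    c("cit", "citrate", "C6H5O7", -3),
    c("icit", "isocitrate", "C6H5O7", -3),
    c("akg", "2-oxoglutarate", "C5H4O5", -2),
    c("oaa", "oxaloacetate", "C4H2O5", -2),
    c("succoa", "succinyl-CoA", "C25H35N7O19P3S", -5),
    c("succ", "succinate", "C4H4O4", -2),
    c("fum", "fumarate", "C4H2O4", -2),
    c("mal__L", "L-malate", "C4H4O5", -2),
    c("6pgl", "6-phosphogluconolactone", "C6H9O9P", -2),
    c("6pgc", "6-phosphogluconate", "C6H10O10P", -3),
    c("q8", "ubiquinone-8", "C49H74O4", 0),
    c("q8h2", "ubiquinol-8", "C49H76O4", 0),
    c("atp", "ATP", "C10H12N5O13P3", -4),
    c("adp", "ADP", "C10H12N5O10P2", -3),
    c("amp", "AMP", "C10H12N5O7P", -2),
    c("pi", "phosphate", "HO4P", -2),
    c("ppi", "diphosphate", "HO7P2", -3),
    c("nad", "NAD+", "C21H26N7O14P2", -1),
    c("nadh", "NADH", "C21H27N7O14P2", -2),
    c("nadp", "NADP+", "C21H25N7O17P3", -3),
    c("nadph", "NADPH", "C21H26N7O17P3", -4),
    c("h", "proton", "H", 1),
    c("h2o", "water", "H2O", 0),
    c("co2", "carbon dioxide", "CO2", 0),
    c("o2", "oxygen", "O2", 0),
    c("nh4", "ammonium", "H4N", 1),
    c("gln__L", "L-glutamine", "C5H10N2O3", 0),
    c("glu__L", "L-glutamate", "C5H8NO4", -1),
    c("ala__L", "L-alanine", "C3H7NO2", 0),
    c("asp__L", "L-aspartate", "C4H6NO4", -1),
    c("asn__L", "L-asparagine", "C4H8N2O3", 0),
    c("lys__L", "L-lysine", "C6H15N2O2", 1),
    c("val__L", "L-valine", "C5H11NO2", 0),
    c("his__L", "L-histidine", "C6H9N3O2", 0),
    c("trp__L", "L-tryptophan", "C11H12N2O2", 0),
    c("phe__L", "L-phenylalanine", "C9H11NO2", 0),
    c("tyr__L", "L-tyrosine", "C9H11NO3", 0),
    c("cys__L", "L-cysteine", "C3H7NO2S", 0),
    c("r5p", "ribose 5-phosphate", "C5H9O8P", -2),
    c("ru5p__D", "ribulose 5-phosphate", "C5H9O8P", -2),
    c("xu5p__D", "xylulose 5-phosphate", "C5H9O8P", -2),
    c("s7p", "sedoheptulose 7-phosphate", "C7H13O10P", -2),
    c("e4p", "erythrose 4-phosphate", "C4H7O7P", -2),
    c("prpp", "5-phospho-alpha-D-ribose 1-diphosphate", "C5H8O14P3", -5),
    c("ura", "uracil", "C4H4N2O2", 0),
    c("ump", "UMP", "C9H11N2O9P", -2),
    c("udp", "UDP", "C9H11N2O12P2", -3),
    c("utp", "UTP", "C9H11N2O15P3", -4),
    c("g1p", "D-glucose 1-phosphate", "C6H11O9P", -2),
    c("udpg", "UDP-glucose", "C15H22N2O17P2", -2),
    c("udpglcur", "UDP-glucuronate", "C15H19N2O18P2", -3),
    c("gam6p", "glucosamine 6-phosphate", "C6H13NO8P", -1),
    c("acgam6p", "N-acetylglucosamine 6-phosphate", "C8H14NO9P", -2),
    c("acgam1p", "N-acetylglucosamine 1-phosphate", "C8H14NO9P", -2),
    c("uacgam", "UDP-N-acetylglucosamine", "C17H25N3O17P2", -2),
    c("ha", "hyaluronan disaccharide unit", "C14H20NO11", -1))
  data.frame(base = d[, 1], name = d[, 2], formula = d[, 3],
             charge = as.integer(d[, 4]))
})

## build the metabolite data.frame for given intracellular/extracellular
## id bases
.makeMetabolites <- function(intra, extra) {
  row_for <- function(base, comp, suffix) {
    i <- match(base, .MET_DATA$base)
    if (is.na(i)) stop("no metabolite data for '", base, "'")
    data.frame(id = paste0(base, suffix), name = .MET_DATA$name[i],
               formula = .MET_DATA$formula[i],
               charge = .MET_DATA$charge[i], compartment = comp)
  }
  rbind(
    do.call(rbind, lapply(intra, row_for, comp = "intracellular",
                          suffix = "_c")),
    do.call(rbind, lapply(extra, row_for, comp = "extracellular",
                          suffix = "_e")))
}

## helper: one reaction row as a character vector
.rxn <- function(id, name, eq, lb, ub, gpr = "", kind = "internal") {
  data.frame(id = id, name = name, equation = eq,
             lb = as.numeric(lb), ub = as.numeric(ub),
             gpr = gpr, kind = kind)
}

## assemble a MetabolicModel from a reaction definition table
.buildModel <- function(rxTab, mets, objective, genomeGeneCount) {
  rx <- data.frame(id = rxTab$id, name = rxTab$name, lb = rxTab$lb,
                   ub = rxTab$ub, gpr = rxTab$gpr, kind = rxTab$kind)
  rx$stoichiometry <- lapply(rxTab$equation, .parseEquation)
  gene_list <- sort(unique(unlist(lapply(rxTab$gpr, gprGenes))))
  MetabolicModel(rx, mets, genes = gene_list,
                 objectiveReaction = objective,
                 genomeGeneCount = genomeGeneCount)
}

## shared central-carbon and HA-branch reactions; `tag` distinguishes the
## gene namespaces of the two organisms
.coreReactions <- function(g) {
  rbind(
    .rxn("GLCt", "glucose permease", "glc__D_e -> glc__D_c",
         0, 1000, g["glcP"], "transport"),
    .rxn("GLK", "hexokinase (glucokinase)",
         "glc__D_c + atp_c -> g6p_c + adp_c + h_c", 0, 1000, g["glk"]),
    .rxn("PTS", "glucose phosphotransferase system",
         "glc__D_e + pep_c -> g6p_c + pyr_c", 0, 1000, g["ptsG"],
         "transport"),
    .rxn("PGI", "glucose-6-phosphate isomerase", "g6p_c <=> f6p_c",
         -1000, 1000, g["pgi"]),
    .rxn("PFK", "phosphofructokinase",
         "f6p_c + atp_c -> fdp_c + adp_c + h_c", 0, 1000, g["pfkA"]),
    .rxn("FBA", "fructose-bisphosphate aldolase",
         "fdp_c <=> dhap_c + g3p_c", -1000, 1000, g["fbaA"]),
    .rxn("TPI", "triose-phosphate isomerase", "dhap_c <=> g3p_c",
         -1000, 1000, g["tpiA"]),
    .rxn("GAPD", "glyceraldehyde-3-phosphate dehydrogenase",
         "g3p_c + nad_c + pi_c <=> 13dpg_c + nadh_c + h_c",
         -1000, 1000, g["gapA"]),
    .rxn("PGK", "phosphoglycerate kinase",
         "13dpg_c + adp_c <=> 3pg_c + atp_c", -1000, 1000, g["pgk"]),
    .rxn("PGM", "phosphoglycerate mutase", "3pg_c <=> 2pg_c",
         -1000, 1000, g["gpmA"]),
    .rxn("ENO", "enolase", "2pg_c <=> pep_c + h2o_c",
         -1000, 1000, g["eno"]),
    .rxn("PYK", "pyruvate kinase",
         "pep_c + adp_c + h_c -> pyr_c + atp_c", 0, 1000, g["pykF"]),
    .rxn("LDH", "D-lactate dehydrogenase",
         "pyr_c + nadh_c + h_c <=> lac__D_c + nad_c",
         -1000, 1000, g["ldh"]),
    .rxn("LACt", "lactate efflux", "lac__D_c -> lac__D_e",
         0, 1000, "", "transport"),
    .rxn("PDH", "pyruvate dehydrogenase complex",
         "pyr_c + coa_c + nad_c -> accoa_c + co2_c + nadh_c",
         0, 1000, paste(g["aceE"], "and", g["aceF"])),
    .rxn("PTAr", "phosphotransacetylase",
         "accoa_c + pi_c <=> actp_c + coa_c", -1000, 1000, g["pta"]),
    .rxn("ACKr", "acetate kinase",
         "actp_c + adp_c <=> ac_c + atp_c", -1000, 1000, g["ackA"]),
    .rxn("ACt", "acetate efflux", "ac_c -> ac_e", 0, 1000, "",
         "transport"),
    .rxn("O2t", "oxygen diffusion", "o2_e <=> o2_c", -1000, 1000, "",
         "transport"),
    .rxn("CS", "citrate synthase",
         "accoa_c + oaa_c + h2o_c -> cit_c + coa_c + h_c",
         0, 1000, g["gltA"]),
    .rxn("ACONT", "aconitase", "cit_c <=> icit_c", -1000, 1000,
         g["acnA"]),
    .rxn("ICDHyr", "isocitrate dehydrogenase (NADP)",
         "icit_c + nadp_c -> akg_c + co2_c + nadph_c", 0, 1000,
         g["icd"]),
    .rxn("PPC", "phosphoenolpyruvate carboxylase",
         "pep_c + co2_c + h2o_c -> oaa_c + pi_c + h_c", 0, 1000,
         g["ppc"]),
    .rxn("GLNS", "glutamine synthetase",
         "glu__L_c + nh4_c + atp_c -> gln__L_c + adp_c + pi_c + h_c",
         0, 1000, g["glnA"]),
    .rxn("ALATA", "alanine transaminase",
         "pyr_c + glu__L_c <=> ala__L_c + akg_c", -1000, 1000,
         g["alaT"]),
    .rxn("ASPTA", "aspartate transaminase",
         "oaa_c + glu__L_c <=> asp__L_c + akg_c", -1000, 1000,
         g["aspC"]),
    .rxn("ASNS", "asparagine synthetase",
         paste("asp__L_c + gln__L_c + atp_c + h2o_c ->",
               "asn__L_c + glu__L_c + amp_c + ppi_c + h_c"),
         0, 1000, g["asnA"]),
    .rxn("LYSS", "lysine biosynthesis (aspartate pathway, lumped)",
         paste("asp__L_c + pyr_c + glu__L_c + atp_c + 2 nadph_c + 3 h_c ->",
               "lys__L_c + akg_c + co2_c + adp_c + pi_c + 2 nadp_c + h2o_c"),
         0, 1000, g["asd"]),
    .rxn("VALS", "valine biosynthesis (lumped)",
         paste("2 pyr_c + glu__L_c + nadph_c + 2 h_c ->",
               "val__L_c + akg_c + co2_c + nadp_c + h2o_c"),
         0, 1000, g["ilvE"]),
    .rxn("RPI", "ribose-5-phosphate isomerase",
         "r5p_c <=> ru5p__D_c", -1000, 1000, g["rpiA"]),
    .rxn("RPE", "ribulose-5-phosphate epimerase",
         "ru5p__D_c <=> xu5p__D_c", -1000, 1000, g["rpe"]),
    .rxn("TKT1", "transketolase 1",
         "r5p_c + xu5p__D_c <=> s7p_c + g3p_c", -1000, 1000, g["tkt"]),
    .rxn("TALA", "transaldolase",
         "s7p_c + g3p_c <=> e4p_c + f6p_c", -1000, 1000, g["talA"]),
    .rxn("TKT2", "transketolase 2",
         "e4p_c + xu5p__D_c <=> f6p_c + g3p_c", -1000, 1000, g["tkt"]),
    .rxn("PRPPS", "phosphoribosylpyrophosphate synthetase",
         "r5p_c + atp_c -> prpp_c + amp_c + h_c", 0, 1000, g["prs"]),
    .rxn("PYRDN", "UMP de novo synthesis (dihydroorotate route, lumped)",
         paste("gln__L_c + asp__L_c + prpp_c + 2 atp_c + nad_c + h2o_c ->",
               "ump_c + glu__L_c + 2 adp_c + 2 pi_c + ppi_c + nadh_c + 3 h_c"),
         0, 1000, g["pyrD"]),
    .rxn("UMPK", "UMP kinase", "ump_c + atp_c <=> udp_c + adp_c",
         -1000, 1000, g["pyrH"]),
    .rxn("NDPK", "nucleoside-diphosphate kinase",
         "udp_c + atp_c <=> utp_c + adp_c", -1000, 1000, g["ndk"]),
    .rxn("ADK", "adenylate kinase", "amp_c + atp_c <=> 2 adp_c",
         -1000, 1000, g["adk"]),
    .rxn("PPA", "inorganic pyrophosphatase",
         "ppi_c + h2o_c -> 2 pi_c + h_c", 0, 1000, g["ppa"]),
    ## --- HA branch (two activated-sugar precursors + synthase) ---
    .rxn("PGMT", "phosphoglucomutase", "g6p_c <=> g1p_c", -1000, 1000,
         g["pgm"]),
    .rxn("GALU", "UTP-glucose-1-phosphate uridylyltransferase",
         "g1p_c + utp_c + h_c -> udpg_c + ppi_c", 0, 1000, g["hasC"]),
    .rxn("UDPGD", "UDP-glucose 6-dehydrogenase",
         "udpg_c + 2 nad_c + h2o_c -> udpglcur_c + 2 nadh_c + 3 h_c",
         0, 1000, g["hasB"]),
    .rxn("GLMS", "glutamine-fructose-6-phosphate transaminase",
         "f6p_c + gln__L_c -> gam6p_c + glu__L_c", 0, 1000, g["glmS"]),
    .rxn("GNA1", "glucosamine-6-phosphate N-acetyltransferase",
         "gam6p_c + accoa_c -> acgam6p_c + coa_c + h_c", 0, 1000,
         g["gna1"]),
    .rxn("PGAMT", "phosphoacetylglucosamine mutase",
         "acgam6p_c <=> acgam1p_c", -1000, 1000, g["glmM"]),
    .rxn("GLMU", "UDP-N-acetylglucosamine pyrophosphorylase",
         "acgam1p_c + utp_c + h_c -> uacgam_c + ppi_c", 0, 1000,
         g["glmU"]),
    .rxn("HAS", "hyaluronan synthase",
         "udpglcur_c + uacgam_c -> ha_c + 2 udp_c + 2 h_c", 0, 1000,
         g["hasA"]),
    .rxn("HAt", "hyaluronan export", "ha_c -> ha_e", 0, 1000, "",
         "transport"),
    ## --- inorganic transport ---
    .rxn("NH4t", "ammonium transport", "nh4_e <=> nh4_c", -1000, 1000,
         "", "transport"),
    .rxn("PIt", "phosphate transport", "pi_e <=> pi_c", -1000, 1000,
         "", "transport"),
    .rxn("CO2t", "CO2 diffusion", "co2_e <=> co2_c", -1000, 1000, "",
         "transport"),
    .rxn("H2Ot", "water diffusion", "h2o_e <=> h2o_c", -1000, 1000, "",
         "transport"),
    .rxn("Ht", "proton diffusion", "h_e <=> h_c", -1000, 1000, "",
         "transport"))
}

.exchange <- function(met, lb, ub = 1000) {
  .rxn(paste0("EX_", met), paste("exchange of", met),
       paste(met, "->"), lb, ub, "", "exchange")
}

## biomass drain: protein + RNA proxy + activated cell-wall sugars + GAM
.biomassReaction <- function(aas, gam, aa_coef = 0.385, ump_coef = 0.372,
                             wall_coef = 0.18) {
  lhs <- c(
    paste(aa_coef, paste0(aas, "_c")),
    paste(ump_coef, "ump_c"),
    paste(wall_coef, "udpg_c"),
    paste(wall_coef, "uacgam_c"),
    paste(gam, "atp_c"),
    paste(gam, "h2o_c"))
  rhs <- c(paste(gam, "adp_c"), paste(gam, "pi_c"), paste(gam, "h_c"))
  .rxn("BIOMASS", "biomass pseudo-reaction",
       paste(paste(lhs, collapse = " + "), "->",
             paste(rhs, collapse = " + ")),
       0, 1000, "", "pseudo")
}

#' Generate the synthetic native-producer model
#'
#' A fermentative, auxotrophic lactic-acid bacterium with an HA branch:
#' EMP glycolysis, lactate fermentation, optional NADH oxidase for
#' aerobic redox relief, truncated TCA (oxidative branch to
#' 2-oxoglutarate only, the sole NADPH source), non-oxidative
#' pentose-phosphate reactions, uracil salvage next to de novo UMP
#' synthesis, amino-acid auxotrophies, alternative sugars (fructose,
#' sucrose, maltose, lactose) and the UDP-glucuronate /
#' UDP-N-acetylglucosamine HA pathway feeding both hyaluronan synthase
#' and the cell-wall share of biomass. The default medium is an
#' anaerobic defined medium: glucose at \code{glucoseUptake}, oxygen
#' closed, auxotrophic amino acids freely available, all other amino
#' acids and uracil transport-capped.
#'
#' @param params a [syntheticModelParams()]; the native defaults apply
#'   when omitted.
#' @return a validated \linkS4class{MetabolicModel} (objective: BIOMASS).
#' @examples
#' m <- makeNativeModel()
#' objectiveValue(fba(m))
#' @export
makeNativeModel <- function(params = syntheticModelParams()) {
  stopifnot(inherits(params, "syntheticModelParams"))
  g <- c(glcP = "glcP_syn", glk = "glk_syn", ptsG = "ptsG_syn",
         pgi = "pgi_syn", pfkA = "pfkA_syn", fbaA = "fbaA_syn",
         tpiA = "tpiA_syn", gapA = "gapA_syn", pgk = "pgk_syn",
         gpmA = "gpmA_syn", eno = "eno_syn", pykF = "pykF_syn",
         ldh = "ldh_syn", aceE = "aceE_syn", aceF = "aceF_syn",
         pta = "pta_syn", ackA = "ackA_syn", gltA = "gltA_syn",
         acnA = "acnA_syn", icd = "icd_syn", ppc = "ppc_syn",
         glnA = "glnA_syn", alaT = "alaT_syn", aspC = "aspC_syn",
         asnA = "asnA_syn", asd = "asd_syn", ilvE = "ilvE_syn",
         rpiA = "rpiA_syn", rpe = "rpe_syn",
         tkt = "tktA_syn or tktB_syn", talA = "talA_syn",
         prs = "prs_syn", pyrD = "pyrD_syn", pyrH = "pyrH_syn",
         ndk = "ndk_syn", adk = "adk_syn", ppa = "ppa_syn",
         pgm = "pgm_syn", hasC = "hasC_syn", hasB = "hasB_syn",
         glmS = "glmS_syn", gna1 = "gna1_syn", glmM = "glmM_syn",
         glmU = "glmU_syn", hasA = "hasA_syn")
  aux <- .AUX_AA[seq_len(params$nAuxotrophies)]
  aas <- c(.SYN_AA, aux)

  rx <- .coreReactions(g)
  ## fermentative NADH oxidase (water-forming), the aerobic redox valve
  if (params$includeNox)
    rx <- rbind(rx, .rxn("NOX", "NADH oxidase (water-forming)",
      "nadh_c + h_c + 0.5 o2_c -> nad_c + h2o_c", 0, 1000, "nox_syn"))
  ## glutamate dehydrogenase: NADH-linked in the fermentative native
  rx <- rbind(rx, .rxn("GDH", "glutamate dehydrogenase (NADH)",
    "akg_c + nh4_c + nadh_c + h_c -> glu__L_c + nad_c + h2o_c",
    0, 1000, "gdhA_syn"))
  ## pyruvate formate-lyase: the anaerobic acetyl-CoA source (PDH's NADH
  ## cannot be reoxidized without oxygen)
  rx <- rbind(rx,
    .rxn("PFL", "pyruvate formate-lyase",
         "pyr_c + coa_c -> accoa_c + for_c", 0, 1000, "pflB_syn"),
    .rxn("FORt", "formate efflux", "for_c -> for_e", 0, 1000, "",
         "transport"),
    .rxn("ADHE", "bifunctional aldehyde-alcohol dehydrogenase",
         "accoa_c + 2 nadh_c + 2 h_c -> etoh_c + coa_c + 2 nad_c",
         0, 1000, "adhE_syn"),
    .rxn("ETOHt", "ethanol efflux", "etoh_c -> etoh_e", 0, 1000, "",
         "transport"))
  ## uracil salvage
  rx <- rbind(rx,
    .rxn("UPP", "uracil phosphoribosyltransferase",
         "ura_c + prpp_c -> ump_c + ppi_c", 0, 1000, "upp_syn"),
    .rxn("URAt", "uracil uptake", "ura_e -> ura_c", 0, 1000, "",
         "transport"))
  ## alternative sugars
  rx <- rbind(rx,
    .rxn("FRUt", "fructose permease", "fru_e -> fru_c", 0, 1000, "",
         "transport"),
    .rxn("FRUK", "fructokinase",
         "fru_c + atp_c -> f6p_c + adp_c + h_c", 0, 1000, "fruK_syn"),
    .rxn("SUCRt", "sucrose permease", "sucr_e -> sucr_c", 0, 1000, "",
         "transport"),
    .rxn("SUCRH", "sucrose hydrolase",
         "sucr_c + h2o_c -> glc__D_c + fru_c", 0, 1000, "sacA_syn"),
    .rxn("MALTt", "maltose permease", "malt_e -> malt_c", 0, 1000, "",
         "transport"),
    .rxn("MALTH", "maltose hydrolase (maltase)",
         "malt_c + h2o_c -> 2 glc__D_c", 0, 1000, "malL_syn"),
    .rxn("LCTSt", "lactose permease", "lcts_e -> lcts_c", 0, 1000, "",
         "transport"),
    .rxn("LCTSH", "beta-galactosidase",
         "lcts_c + h2o_c -> glc__D_c + gal_c", 0, 1000, "lacZ_syn"),
    .rxn("GALKL", "galactose utilization (Leloir, lumped)",
         "gal_c + atp_c -> g1p_c + adp_c + h_c", 0, 1000, "galK_syn"))
  ## amino-acid transporters
  for (aa in aas)
    rx <- rbind(rx, .rxn(paste0(toupper(substr(aa, 1, 3)), "t"),
      paste("uptake of", aa), paste0(aa, "_e -> ", aa, "_c"),
      0, 1000, "", "transport"))
  ## maintenance + biomass
  rx <- rbind(rx,
    .rxn("ATPM", "ATP maintenance (NGAM)",
         "atp_c + h2o_c -> adp_c + pi_c + h_c", params$ngam, 1000, "",
         "pseudo"),
    .biomassReaction(aas, params$gam))
  ## exchanges: anaerobic defined medium with capped supplementation
  caps <- stats::setNames(rep(-.AA_CAP, length(.SYN_AA)), .SYN_AA)
  caps["asp__L"] <- -.ASP_CAP
  rx <- rbind(rx,
    .exchange("glc__D_e", -params$glucoseUptake),
    .exchange("o2_e", 0),
    .exchange("co2_e", -1000),
    .exchange("h2o_e", -1000),
    .exchange("h_e", -1000),
    .exchange("pi_e", -10),
    .exchange("nh4_e", -10),
    .exchange("ura_e", -.URA_CAP),
    .exchange("lac__D_e", 0),
    .exchange("for_e", 0),
    .exchange("etoh_e", 0),
    .exchange("ac_e", 0),
    .exchange("ha_e", 0),
    .exchange("fru_e", 0),
    .exchange("sucr_e", 0),
    .exchange("malt_e", 0),
    .exchange("lcts_e", 0))
  for (aa in .SYN_AA)
    rx <- rbind(rx, .exchange(paste0(aa, "_e"), caps[[aa]]))
  for (aa in aux)
    rx <- rbind(rx, .exchange(paste0(aa, "_e"), -10))

  intra <- c("glc__D", "fru", "gal", "sucr", "malt", "lcts", "g6p",
             "f6p", "fdp", "dhap", "g3p", "13dpg", "3pg", "2pg", "pep",
             "pyr", "lac__D", "for", "etoh", "accoa", "coa", "actp", "ac",
             "cit",
             "icit", "akg", "oaa", "atp", "adp", "amp", "pi", "ppi",
             "nad", "nadh", "nadp", "nadph", "h", "h2o", "co2", "o2",
             "nh4", "r5p", "ru5p__D", "xu5p__D", "s7p", "e4p", "prpp",
             "ura", "ump", "udp", "utp", "g1p", "udpg", "udpglcur",
             "gam6p", "acgam6p", "acgam1p", "uacgam", "ha", aas)
  extra <- c("glc__D", "fru", "sucr", "malt", "lcts", "o2", "co2",
             "h2o", "h", "pi", "nh4", "ura", "lac__D", "for", "etoh", "ac", "ha",
             aas)
  mets <- .makeMetabolites(intra, extra)
  model <- .buildModel(rx, mets, "BIOMASS", 2049L)
  attr(model, "params") <- params
  model
}

#' Generate the synthetic recombinant-producer model
#'
#' A prototrophic respiring host carrying the HA pathway as a
#' heterologous module: EMP glycolysis, oxidative pentose-phosphate
#' branch (G6P dehydrogenase analog \code{zwf_syn}), complete Krebs
#' cycle, electron transport chain (NADH dehydrogenase, cytochrome
#' oxidase, proton-coupled ATP synthase), NADPH-linked glutamate
#' dehydrogenase feeding all amino-acid biosynthesis, and de novo
#' pyrimidine synthesis. The default medium is an aerobic minimal
#' medium: glucose at \code{glucoseUptake} (default 4.67), ammonium,
#' phosphate and oxygen.
#'
#' @param params a [syntheticModelParams()]; when omitted, recombinant
#'   defaults are used (glucose 4.67, oxidative PPP and full TCA on).
#' @return a validated \linkS4class{MetabolicModel} (objective: BIOMASS).
#' @examples
#' m <- makeRecombinantModel()
#' objectiveValue(fba(m))
#' @export
makeRecombinantModel <- function(params = syntheticModelParams(
    glucoseUptake = 4.67, includeOxidativePpp = TRUE,
    includeFullTca = TRUE, includeNox = FALSE, nAuxotrophies = 0L)) {
  stopifnot(inherits(params, "syntheticModelParams"))
  g <- c(glcP = "glcP_cg", glk = "glk_cg", ptsG = "ptsG_cg",
         pgi = "pgi_cg", pfkA = "pfkA_cg", fbaA = "fbaA_cg",
         tpiA = "tpiA_cg", gapA = "gapA_cg", pgk = "pgk_cg",
         gpmA = "gpmA_cg", eno = "eno_cg", pykF = "pykF_cg",
         ldh = "ldh_cg", aceE = "aceE_cg", aceF = "aceF_cg",
         pta = "pta_cg", ackA = "ackA_cg", gltA = "gltA_cg",
         acnA = "acnA_cg", icd = "icd_cg", ppc = "ppc_cg",
         glnA = "glnA_cg", alaT = "alaT_cg", aspC = "aspC_cg",
         asnA = "asnA_cg", asd = "asd_cg", ilvE = "ilvE_cg",
         rpiA = "rpiA_cg", rpe = "rpe_cg", tkt = "tktA_cg",
         talA = "talA_cg", prs = "prs_cg", pyrD = "pyrD_cg",
         pyrH = "pyrH_cg", ndk = "ndk_cg", adk = "adk_cg",
         ppa = "ppa_cg", pgm = "pgm_cg", hasC = "galU_cg",
         hasB = "hasB_het", glmS = "glmS_cg", gna1 = "gna1_cg",
         glmM = "glmM_cg", glmU = "glmU_cg", hasA = "hasA_het")
  rx <- .coreReactions(g)
  ## NADPH-linked glutamate dehydrogenase (prototroph workhorse)
  rx <- rbind(rx, .rxn("GDH", "glutamate dehydrogenase (NADPH)",
    "akg_c + nh4_c + nadph_c + h_c -> glu__L_c + nadp_c + h2o_c",
    0, 1000, "gdh_cg"))
  if (params$includeOxidativePpp)
    rx <- rbind(rx,
      .rxn("ZWF", "glucose-6-phosphate dehydrogenase",
           "g6p_c + nadp_c -> 6pgl_c + nadph_c + h_c", 0, 1000,
           "zwf_syn"),
      .rxn("PGL", "6-phosphogluconolactonase",
           "6pgl_c + h2o_c -> 6pgc_c + h_c", 0, 1000, "pgl_cg"),
      .rxn("GND", "6-phosphogluconate dehydrogenase",
           "6pgc_c + nadp_c -> ru5p__D_c + co2_c + nadph_c", 0, 1000,
           "gnd_cg"))
  if (params$includeFullTca)
    rx <- rbind(rx,
      .rxn("AKGDH", "2-oxoglutarate dehydrogenase complex",
           "akg_c + coa_c + nad_c -> succoa_c + co2_c + nadh_c",
           0, 1000, "sucA_cg and sucB_cg"),
      .rxn("SUCOAS", "succinyl-CoA synthetase",
           "succoa_c + adp_c + pi_c <=> succ_c + coa_c + atp_c",
           -1000, 1000, "sucCD_cg"),
      .rxn("SUCDH", "succinate dehydrogenase",
           "succ_c + q8_c -> fum_c + q8h2_c", 0, 1000, "sdhA_cg"),
      .rxn("FUM", "fumarase", "fum_c + h2o_c <=> mal__L_c",
           -1000, 1000, "fumC_cg"),
      .rxn("MDH", "malate dehydrogenase",
           "mal__L_c + nad_c <=> oaa_c + nadh_c + h_c", -1000, 1000,
           "mdh_cg"),
      ## electron transport + ATP synthase, lumped at fixed P/O ratios
      ## (2 ATP per NADH, 1 per quinol); a pumped-proton formulation in a
      ## two-compartment model would allow a futile proton loop
      .rxn("NADHOX", "NADH oxidative phosphorylation (lumped, P/O 2)",
           paste("nadh_c + 0.5 o2_c + 2 adp_c + 2 pi_c + 3 h_c ->",
                 "nad_c + 2 atp_c + 3 h2o_c"),
           0, 1000, "nuo_cg and ctaD_cg and atpA_cg"),
      .rxn("QOX", "quinol oxidative phosphorylation (lumped, P/O 1)",
           paste("q8h2_c + 0.5 o2_c + adp_c + pi_c + h_c ->",
                 "q8_c + atp_c + 2 h2o_c"),
           0, 1000, "ctaD_cg and atpA_cg"))
  rx <- rbind(rx,
    .rxn("ATPM", "ATP maintenance (NGAM)",
         "atp_c + h2o_c -> adp_c + pi_c + h_c", params$ngam, 1000, "",
         "pseudo"),
    .biomassReaction(.SYN_AA, params$gam, aa_coef = 0.71,
                     ump_coef = 0.40, wall_coef = 0.194))
  rx <- rbind(rx,
    .exchange("glc__D_e", -params$glucoseUptake),
    .exchange("o2_e", -1000),
    .exchange("co2_e", -1000),
    .exchange("h2o_e", -1000),
    .exchange("h_e", -1000),
    .exchange("pi_e", -10),
    .exchange("nh4_e", -10),
    .exchange("lac__D_e", 0),
    .exchange("ac_e", 0),
    .exchange("ha_e", 0))
  intra <- c("glc__D", "g6p", "f6p", "fdp", "dhap", "g3p", "13dpg",
             "3pg", "2pg", "pep", "pyr", "lac__D", "accoa", "coa",
             "actp", "ac", "cit", "icit", "akg", "oaa", "succoa",
             "succ", "fum", "mal__L", "6pgl", "6pgc", "q8", "q8h2",
             "atp", "adp", "amp", "pi", "ppi", "nad", "nadh", "nadp",
             "nadph", "h", "h2o", "co2", "o2", "nh4", "r5p", "ru5p__D",
             "xu5p__D", "s7p", "e4p", "prpp", "ump", "udp", "utp",
             "g1p", "udpg", "udpglcur", "gam6p", "acgam6p", "acgam1p",
             "uacgam", "ha", .SYN_AA)
  extra <- c("glc__D", "o2", "co2", "h2o", "h", "pi", "nh4", "lac__D",
             "ac", "ha")
  mets <- .makeMetabolites(intra, extra)
  model <- .buildModel(rx, mets, "BIOMASS", 3058L)
  attr(model, "params") <- params
  model
}

#' Printed validation fixture: screens with experimental labels
#'
#' Returns the amino-acid essentiality screen (22 conditions) and the
#' carbon-source screen (6 conditions) with their experimental and
#' model-predicted growth labels as published, phenotype-classified by
#' [derivePhenotypes()]: growth (G) is the positive class, so an
#' experimental NG predicted as G is a false positive.
#'
#' @return list with data.frames \code{aminoAcids} and
#'   \code{carbonSources}, each with columns \code{condition},
#'   \code{experimental}, \code{predicted}, \code{phenotype}.
#' @examples
#' fx <- makeValidationFixture()
#' tallyPhenotypes(fx$aminoAcids)
#' @export
makeValidationFixture <- function() {
  aa <- data.frame(
    condition = c("CDM1", "CDM1-Asp", "CDM1-Asn", "CDM1-Lys",
                  "CDM1-Met", "CDM1-Thr", "CDM1-Ile", "CDM1-Ala",
                  "CDM1-Val", "CDM1-Leu", "CDM1-Tyr", "CDM1-Phe",
                  "CDM1-Trp", "CDM1-Ser", "CDM1-Gly", "CDM1-Cys",
                  "CDM1-Glu", "CDM1-Pro", "CDM1-Orn", "CDM1-Arg",
                  "CDM1-His", "CDM1-Gln"),
    experimental = c("G", "G", "G", "NG", "NG", "G", "NG", "G", "NG",
                     "NG", "NG", "NG", "G", "G", "G", "NG", "G", "G",
                     "G", "NG", "NG", "NG"),
    predicted = c("G", "G", "G", "G", "NG", "G", "NG", "G", "NG",
                  "NG", "NG", "NG", "G", "G", "G", "NG", "G", "G",
                  "G", "NG", "NG", "G"))
  cs <- data.frame(
    condition = c("No sugar", "Glucose", "Sucrose", "Fructose",
                  "Maltose", "Lactose"),
    experimental = c("NG", "G", "G", "G", "G", "G"),
    predicted = c("NG", "G", "G", "G", "G", "G"))
  list(aminoAcids = derivePhenotypes(aa), carbonSources = derivePhenotypes(cs))
}
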