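## Shared fixtures and memoized heavy computations. Everything is built
## in code; nothing is read from disk.

.memo <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .memo)) assign(key, force(expr), envir = .memo)
  get(key, envir = .memo)
}

native_model <- function() memoize("native", makeNativeModel())

recombinant_model <- function() memoize("recomb", makeRecombinantModel())

## the strain-design condition: defined medium with oxygen available
aerobic_native <- function() memoize("native_aerobic", {
  m <- makeNativeModel()
  bounds(m, "EX_o2_e") <- c(-10, 1000)
  m
})

aerobic_reference <- function() memoize("native_ref",
  referenceState(aerobic_native()))

native_singles <- function() memoize("native_singles",
  singleGeneDeletion(native_model()))

native_doubles <- function() memoize("native_doubles",
  doubleGeneDeletion(native_model(), singles = native_singles()))

## ---- tiny hand-built models ---------------------------------------------

simple_metabolites <- function(intra, extra = character(0)) {
  mk <- function(ids, comp) if (length(ids)) data.frame(
    id = ids, name = ids, formula = "", charge = 0L, compartment = comp)
    else NULL
  rbind(mk(intra, "intracellular"), mk(extra, "extracellular"))
}

simple_reaction <- function(id, stoich, lb, ub, gpr = "",
                            kind = "internal") {
  rx <- data.frame(id = id, name = id, lb = lb, ub = ub, gpr = gpr,
                   kind = kind)
  rx$stoichiometry <- list(stoich)
  rx
}

## linear chain: EX_a (uptake up to 10) -> a_e -> a -> biomass drain that
## burns 10 a per unit growth, so optimal growth is uptake / 10
chain_model <- function(uptake = 10) {
  rx <- rbind(
    simple_reaction("EX_a", c(a_e = -1), -uptake, 1000, kind = "exchange"),
    simple_reaction("At", c(a_e = -1, a = 1), 0, 1000, kind = "transport"),
    simple_reaction("GROWTH", c(a = -10), 0, 1000, kind = "pseudo"))
  MetabolicModel(rx, simple_metabolites("a", "a_e"),
                 objectiveReaction = "GROWTH")
}

## diamond: two equal-yield branches from a to b
diamond_model <- function() {
  rx <- rbind(
    simple_reaction("EX_a", c(a_e = -1), -10, 1000, kind = "exchange"),
    simple_reaction("At", c(a_e = -1, a = 1), 0, 1000, kind = "transport"),
    simple_reaction("B1", c(a = -1, b = 1), 0, 1000, "g1"),
    simple_reaction("B2", c(a = -1, b = 1), 0, 1000, "g2"),
    simple_reaction("GROWTH", c(b = -1), 0, 1000, kind = "pseudo"))
  MetabolicModel(rx, simple_metabolites(c("a", "b"), "a_e"),
                 genes = c("g1", "g2"), objectiveReaction = "GROWTH")
}

## random small models for solver cross-checks; returns a list of LP
## problem descriptions (S, lb, ub, objective index)
random_lp_cases <- function(n_cases, seed, max_rxn = 15) {
  set.seed(seed)
  lapply(seq_len(n_cases), function(i) {
    m <- sample(3:8, 1); n <- sample(6:max_rxn, 1)
    S <- matrix(sample(-2:2, m * n, TRUE), m, n)
    lb <- ifelse(runif(n) < 0.4, -10, 0)
    ub <- rep(10, n)
    list(S = S, lb = lb, ub = ub, obj = sample(n, 1))
  })
}
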