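## Independent oracles.
##
## Cross-checks go through implementations that share no code with the
## package: scipy's HiGHS solver for linear programs, scipy SLSQP for
## quadratic MOMA projections, and a from-scratch elemental tally for
## balance checking.

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  p
}

## batch-solve LPs (maximize obj'v s.t. S v = 0, lb <= v <= ub) with
## scipy HiGHS; cases is a list of list(S, lb, ub, obj = index or vector)
scipy_lp_batch <- function(cases) {
  dir <- tempfile("lpcases"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  payload <- lapply(cases, function(cs) {
    obj <- if (length(cs$obj) == 1L) {
      o <- numeric(ncol(cs$S)); o[cs$obj] <- 1; o
    } else cs$obj
    list(S = unname(apply(cs$S, 1, as.numeric, simplify = FALSE)),
         lb = as.numeric(cs$lb), ub = as.numeric(cs$ub),
         obj = as.numeric(obj))
  })
  jsonlite::write_json(payload, file.path(dir, "cases.json"),
                       digits = NA, auto_unbox = FALSE)
  script <- file.path(dir, "solve.py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "cases = json.load(open(sys.argv[1]))",
    "out = []",
    "for cs in cases:",
    "    S = np.array(cs['S'], dtype=float)",
    "    obj = np.array(cs['obj'], dtype=float)",
    "    r = linprog(-obj, A_eq=S, b_eq=np.zeros(S.shape[0]),",
    "                bounds=list(zip(cs['lb'], cs['ub'])), method='highs')",
    "    out.append({'ok': bool(r.success),",
    "                'val': float(-r.fun) if r.success else None})",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  outfile <- file.path(dir, "out.json")
  status <- system2(python_bin(), c(script, file.path(dir, "cases.json"),
                                    outfile), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop("scipy LP oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

## batch-solve quadratic MOMA projections with scipy SLSQP:
## min ||v - ref||^2 s.t. S v = 0, lb <= v <= ub
scipy_qp_batch <- function(cases) {
  dir <- tempfile("qpcases"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  payload <- lapply(cases, function(cs)
    list(S = unname(apply(cs$S, 1, as.numeric, simplify = FALSE)),
         lb = as.numeric(cs$lb), ub = as.numeric(cs$ub),
         ref = as.numeric(cs$ref)))
  jsonlite::write_json(payload, file.path(dir, "cases.json"),
                       digits = NA, auto_unbox = FALSE)
  script <- file.path(dir, "solve.py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import minimize, linprog, LinearConstraint",
    "cases = json.load(open(sys.argv[1]))",
    "out = []",
    "for cs in cases:",
    "    S = np.array(cs['S'], dtype=float)",
    "    ref = np.array(cs['ref'], dtype=float)",
    "    lb = np.array(cs['lb'], dtype=float)",
    "    ub = np.array(cs['ub'], dtype=float)",
    "    n = len(ref)",
    "    feas = linprog(np.zeros(n), A_eq=S, b_eq=np.zeros(S.shape[0]),",
    "                   bounds=list(zip(lb, ub)), method='highs')",
    "    x0 = feas.x if feas.success else np.clip(np.zeros(n), lb, ub)",
    "    cons = [{'type': 'eq', 'fun': lambda v: S @ v,",
    "             'jac': lambda v: S}]",
    "    r = minimize(lambda v: np.sum((v - ref) ** 2), x0,",
    "                 jac=lambda v: 2 * (v - ref), method='SLSQP',",
    "                 bounds=list(zip(lb, ub)), constraints=cons,",
    "                 options={'maxiter': 1000, 'ftol': 1e-14})",
    "    if not r.success:",
    "        # drop linearly dependent rows of S for the fallback",
    "        from scipy.linalg import qr as sqr",
    "        Q, R, P = sqr(S.T, pivoting=True)",
    "        rank = int(np.sum(np.abs(np.diag(np.atleast_2d(R))) > 1e-10))",
    "        Sred = S[P[:rank]]",
    "        try:",
    "            r = minimize(lambda v: np.sum((v - ref) ** 2), x0,",
    "                         jac=lambda v: 2 * (v - ref),",
    "                         method='trust-constr',",
    "                         bounds=list(zip(lb, ub)),",
    "                         constraints=[LinearConstraint(Sred, 0, 0)],",
    "                         options={'maxiter': 3000, 'gtol': 1e-12,",
    "                                  'xtol': 1e-14})",
    "            ok = r.status in (1, 2)",
    "        except Exception:",
    "            ok = False",
    "    else:",
    "        ok = True",
    "    out.append({'ok': bool(ok), 'dist': float(r.fun),",
    "                'v': [float(x) for x in r.x]})",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  outfile <- file.path(dir, "out.json")
  status <- system2(python_bin(), c(script, file.path(dir, "cases.json"),
                                    outfile), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop("scipy QP oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

## from-scratch element tally, independent of the package's parser:
## returns named residual vector (elements + "charge") for one reaction
oracle_balance <- function(model, rxn_id) {
  rx <- reactions(model)
  mets <- metabolites(model)
  st <- rx$stoichiometry[[match(rxn_id, rx$id)]]
  resid <- c(charge = 0)
  for (k in seq_along(st)) {
    mi <- match(names(st)[k], mets$id)
    f <- mets$formula[mi]
    ## tokenize formula character by character
    chars <- strsplit(f, "")[[1]]
    i <- 1
    while (i <= length(chars)) {
      el <- chars[i]; i <- i + 1
      while (i <= length(chars) && grepl("[a-z]", chars[i])) {
        el <- paste0(el, chars[i]); i <- i + 1
      }
      num <- ""
      while (i <= length(chars) && grepl("[0-9]", chars[i])) {
        num <- paste0(num, chars[i]); i <- i + 1
      }
      cnt <- if (nzchar(num)) as.numeric(num) else 1
      resid[el] <- (if (el %in% names(resid)) resid[[el]] else 0) +
        st[[k]] * cnt
    }
    resid[["charge"]] <- resid[["charge"]] + st[[k]] * mets$charge[mi]
  }
  resid
}
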