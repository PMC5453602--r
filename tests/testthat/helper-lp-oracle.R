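# Independent LP oracle: scipy.optimize.linprog (HiGHS) driven through the
# system python. Solves a batch of problems in one interpreter call and
# returns status/objective per problem. Used only to cross-check the
# package's internal simplex, never as the implementation.

scipy_lp_available <- function() nzchar(Sys.which("python"))

scipy_lp_batch <- function(problems) {
  stopifnot(scipy_lp_available())
  clean <- lapply(problems, function(p) {
    ub <- p$ub; ub[!is.finite(ub)] <- 1e9
    list(obj = as.numeric(p$obj),
         Aeq = if (is.null(p$Aeq)) NULL else lapply(seq_len(nrow(as.matrix(p$Aeq))), function(i) as.numeric(as.matrix(p$Aeq)[i, ])),
         beq = if (is.null(p$beq)) NULL else as.numeric(p$beq),
         Aub = if (is.null(p$Aub)) NULL else lapply(seq_len(nrow(as.matrix(p$Aub))), function(i) as.numeric(as.matrix(p$Aub)[i, ])),
         bub = if (is.null(p$bub)) NULL else as.numeric(p$bub),
         lb = as.numeric(p$lb), ub = as.numeric(ub),
         maximize = isTRUE(p$maximize))
  })
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  pyfile <- tempfile(fileext = ".py")
  jsonlite::write_json(clean, infile, digits = NA, auto_unbox = TRUE,
                       null = "null")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "probs = json.load(open(sys.argv[1]))",
    "out = []",
    "for p in probs:",
    "    c = np.asarray(p['obj'], float)",
    "    sgn = -1.0 if p['maximize'] else 1.0",
    "    res = linprog(sgn * c,",
    "                  A_eq=None if p['Aeq'] is None else np.asarray(p['Aeq'], float),",
    "                  b_eq=None if p['beq'] is None else np.asarray(p['beq'], float),",
    "                  A_ub=None if p['Aub'] is None else np.asarray(p['Aub'], float),",
    "                  b_ub=None if p['bub'] is None else np.asarray(p['bub'], float),",
    "                  bounds=list(zip(p['lb'], p['ub'])), method='highs')",
    "    status = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(res.status, 'other')",
    "    obj = sgn * res.fun if res.status == 0 else None",
    "    out.append({'status': status, 'objective': obj})",
    "json.dump(out, open(sys.argv[2], 'w'))"), pyfile)
  rc <- system2("python", c(pyfile, infile, outfile), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop("scipy oracle failed: ", paste(rc, collapse = "\n"))
  jsonlite::fromJSON(outfile, simplifyDataFrame = FALSE)
}

# FBA problem for the oracle from a stoich_model
oracle_fba_problem <- function(model) {
  obj <- numeric(length(model$reaction_ids))
  obj[match(model$objective, model$reaction_ids)] <- 1
  list(obj = obj, Aeq = as.matrix(model$S), beq = rep(0, nrow(model$S)),
       lb = model$lb, ub = model$ub, maximize = TRUE)
}

# FVA subproblem (direction = "min"/"max" for reaction j)
oracle_fva_problem <- function(model, j, direction) {
  obj <- numeric(length(model$reaction_ids))
  obj[j] <- 1
  list(obj = obj, Aeq = as.matrix(model$S), beq = rep(0, nrow(model$S)),
       lb = model$lb, ub = model$ub, maximize = direction == "max")
}
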