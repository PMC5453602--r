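# Gene-protein-reaction (GPR) boolean rules.
#
# Grammar:  expr   := term ("or" term)*
#           term   := factor ("and" factor)*
#           factor := "(" expr ")" | gene
# Keywords are case-insensitive; gene identifiers are case-sensitive opaque
# strings. The empty rule means "no gene requirement".

parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("GPR parse error in rule '", rule, "': unexpected end")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")"))
        stop("GPR parse error in rule '", rule, "': unbalanced parentheses")
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("GPR parse error in rule '", rule, "': unexpected token '", t, "'")
    t
  }
  ast <- parse_expr()
  if (!is.na(peek()))
    stop("GPR parse error in rule '", rule, "': trailing token '", peek(), "'")
  ast
}

gpr_ast_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (is.character(ast)) return(ast)
  unique(unlist(lapply(ast$args, gpr_ast_genes)))
}

# AND -> min, OR -> max. With 0/1 values this is boolean evaluation; with
# probabilities it is the retention-probability propagation rule (a complex
# is as available as its scarcest subunit, isozymes as its most available).
eval_gpr_ast <- function(ast, values, missing = c("error", "one")) {
  missing <- match.arg(missing)
  if (is.null(ast)) return(1)
  if (is.character(ast)) {
    v <- values[[ast]]
    if (is.null(v) || is.na(v)) {
      if (missing == "error") stop("gene '", ast, "' has no state in gene_states")
      return(1)
    }
    return(v)
  }
  vals <- vapply(ast$args, eval_gpr_ast, numeric(1),
                 values = values, missing = missing)
  if (ast$op == "and") min(vals) else max(vals)
}

#' Evaluate a gene-protein-reaction rule
#'
#' Evaluates a boolean GPR expression (\code{and}/\code{or}/parentheses over
#' gene identifiers) under a given 0/1 gene-state assignment. The empty rule
#' evaluates to 1: a reaction with no gene requirement is unaffected by gene
#' deletions.
#'
#' @param rule character GPR expression, possibly empty.
#' @param gene_states named numeric or logical vector (or list) of 0/1 states;
#'   every gene in the rule must be present.
#' @return 0 or 1.
#' @examples
#' evaluate_gpr("(g1 and g2)", c(g1 = 1, g2 = 0))  # 0
#' evaluate_gpr("g1 or g2", c(g1 = 0, g2 = 1))     # 1
#' evaluate_gpr("", c(g1 = 0))                      # 1
#' @export
evaluate_gpr <- function(rule, gene_states) {
  ast <- parse_gpr(rule)
  vals <- as.list(as.numeric(gene_states))
  names(vals) <- names(gene_states)
  res <- eval_gpr_ast(ast, vals, missing = "error")
  as.numeric(res >= 0.5)
}
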