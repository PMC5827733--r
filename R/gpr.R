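# Gene-protein-reaction rule parsing and evaluation.
#
# Grammar:  expr := term ('or' term)* ; term := factor ('and' factor)* ;
#           factor := gene-id | '(' expr ')'
# Evaluation over expression scores follows the usual enzyme-complex
# semantics: AND -> min (a complex is limited by its scarcest subunit),
# OR -> max (isozymes are interchangeable). Genes absent from the profile
# are excluded from min/max; a rule whose genes are all unknown scores NA.

gpr_tokenize <- function(gpr) {
  gpr <- gsub("([()])", " \\1 ", gpr)
  tokens <- strsplit(trimws(gpr), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

gpr_parse <- function(gpr) {
  tokens <- gpr_tokenize(gpr)
  if (length(tokens) == 0L) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { tok <- tokens[pos]; pos <<- pos + 1L; tok }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && tolower(peek()) %in% c("or", "|", "||")) {
      advance()
      node <- list(op = "or", args = list(node, parse_term()))
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) %in% c("and", "&", "&&")) {
      advance()
      node <- list(op = "and", args = list(node, parse_factor()))
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok))
      dmoma_stop("dmoma_gpr_error", paste0("truncated GPR rule: '", gpr, "'"))
    if (tok == "(") {
      advance()
      node <- parse_expr()
      if (!identical(peek(), ")"))
        dmoma_stop("dmoma_gpr_error",
                   paste0("unbalanced parentheses in GPR rule: '", gpr, "'"))
      advance()
      return(node)
    }
    if (tok %in% c(")") || tolower(tok) %in% c("and", "or"))
      dmoma_stop("dmoma_gpr_error",
                 paste0("malformed GPR rule: '", gpr, "'"))
    advance()
    list(op = "gene", id = tok)
  }
  node <- parse_expr()
  if (pos <= length(tokens))
    dmoma_stop("dmoma_gpr_error",
               paste0("trailing tokens in GPR rule: '", gpr, "'"))
  node
}

gpr_eval <- function(node, scores) {
  if (is.null(node)) return(NA_real_)
  if (node$op == "gene") {
    if (node$id %in% names(scores)) return(scores[[node$id]])
    return(NA_real_)
  }
  vals <- vapply(node$args, gpr_eval, numeric(1), scores = scores)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (node$op == "and") min(vals) else max(vals)
}

gpr_genes <- function(node) {
  if (is.null(node)) return(character(0))
  if (node$op == "gene") return(node$id)
  unique(unlist(lapply(node$args, gpr_genes)))
}
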