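#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with `and` / `or`
#' connectives and parentheses, e.g. `"(MTR and MTRR) or MMUT"`. Keywords are
#' matched case-insensitively; gene identifiers are case-sensitive. The empty
#' string parses to the empty rule, meaning the reaction is not
#' gene-associated and can never be disabled by a gene deletion.
#'
#' @param text A single GPR string.
#' @return An object of class `gpr_rule`: a tree whose nodes are lists with
#'   `op` (`"and"`, `"or"`, `"gene"`, or `"empty"`) and either `children`
#'   (sub-rules) or `gene` (a leaf identifier).
#' @examples
#' parse_gpr("(MTR and MTRR)")
#' parse_gpr("")
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (is.na(text) || !nzchar(text)) {
    return(structure(list(op = "empty"), class = "gpr_rule"))
  }
  toks <- gpr_tokenize(text)
  st <- list(pos = 1L, toks = toks)
  res <- gpr_parse_or(st)
  if (res$state$pos <= length(toks)) {
    bad <- toks[[res$state$pos]]
    stop("malformed GPR: unexpected token '", bad$value,
         "' at position ", bad$at, call. = FALSE)
  }
  structure(res$node, class = "gpr_rule")
}

gpr_tokenize <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, at = i)
      i <- i + 1L
      next
    }
    mrest <- regmatches(substr(text, i, n),
                        regexpr("^[^()[:space:]]+", substr(text, i, n)))
    word <- mrest[1]
    type <- if (tolower(word) %in% c("and", "or")) tolower(word) else "gene"
    toks[[length(toks) + 1L]] <- list(type = type, value = word, at = i)
    i <- i + nchar(word)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st) {
  left <- gpr_parse_and(st)
  st <- left$state
  kids <- list(left$node)
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_and(st)
    st <- nxt$state
    kids[[length(kids) + 1L]] <- nxt$node
  }
  node <- if (length(kids) == 1L) kids[[1L]] else list(op = "or", children = kids)
  list(node = node, state = st)
}

gpr_parse_and <- function(st) {
  left <- gpr_parse_atom(st)
  st <- left$state
  kids <- list(left$node)
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_atom(st)
    st <- nxt$state
    kids[[length(kids) + 1L]] <- nxt$node
  }
  node <- if (length(kids) == 1L) kids[[1L]] else list(op = "and", children = kids)
  list(node = node, state = st)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.null(tk)) stop("malformed GPR: unexpected end of expression", call. = FALSE)
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    st <- inner$state
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != ")") {
      stop("malformed GPR: unmatched '(' opened at position ", tk$at, call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(list(node = inner$node, state = st))
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(list(node = list(op = "gene", gene = tk$value), state = st))
  }
  stop("malformed GPR: unexpected token '", tk$value, "' at position ",
       tk$at, call. = FALSE)
}

#' Evaluate a GPR rule under a set of deleted genes
#'
#' Mirrors the knockout semantics of constraint-based modeling toolboxes:
#' a leaf is `TRUE` when its gene is *not* deleted, `and` is conjunction,
#' `or` is disjunction, and the empty rule is always `TRUE` (reactions
#' without gene association are never disabled by a deletion).
#'
#' @param rule A `gpr_rule` (or a GPR string, parsed on the fly).
#' @param deleted Character vector of deleted gene identifiers.
#' @return `TRUE` if the reaction retains function, otherwise `FALSE`.
#' @examples
#' evaluate_gpr(parse_gpr("MMUT"), "MMUT")
#' evaluate_gpr("(A or B)", "A")
#' @export
evaluate_gpr <- function(rule, deleted = character()) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  eval_node <- function(nd) {
    switch(nd$op,
      empty = TRUE,
      gene  = !(nd$gene %in% deleted),
      and   = all(vapply(nd$children, eval_node, logical(1))),
      or    = any(vapply(nd$children, eval_node, logical(1))),
      stop("unknown GPR node op: ", nd$op)
    )
  }
  eval_node(rule)
}

#' Genes referenced by a GPR rule
#' @param rule A `gpr_rule` or GPR string.
#' @return Character vector of unique gene identifiers (empty for the empty rule).
#' @export
gpr_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  walk <- function(nd) {
    switch(nd$op,
      empty = character(),
      gene  = nd$gene,
      unlist(lapply(nd$children, walk))
    )
  }
  unique(walk(rule))
}

#' Serialize a GPR rule back to text
#' @param rule A `gpr_rule`.
#' @return A GPR string logically equivalent to the parsed input.
#' @export
format_gpr <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  fmt <- function(nd, parent_op = "") {
    switch(nd$op,
      empty = "",
      gene  = nd$gene,
      {
        inner <- vapply(nd$children, fmt, character(1), parent_op = nd$op)
        out <- paste(inner, collapse = paste0(" ", nd$op, " "))
        if (nzchar(parent_op) && parent_op != nd$op) paste0("(", out, ")") else out
      }
    )
  }
  fmt(rule)
}

#' @export
print.gpr_rule <- function(x, ...) {
  txt <- format_gpr(x)
  cat("<gpr_rule> ", if (nzchar(txt)) txt else "(empty)", "\n", sep = "")
  invisible(x)
}

# Three-valued evaluation used for expression-based reaction scoring:
# statuses are numeric (0 inactive, 1 unknown, 2 active); AND -> min,
# OR -> max, empty rule -> unknown.
gpr_score <- function(rule, status) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  ev <- function(nd) {
    switch(nd$op,
      empty = 1,
      gene  = if (nd$gene %in% names(status)) status[[nd$gene]] else 1,
      and   = min(vapply(nd$children, ev, numeric(1))),
      or    = max(vapply(nd$children, ev, numeric(1)))
    )
  }
  ev(rule)
}

# Quantitative evaluation used by eFlux: AND -> min (limiting subunit),
# OR -> sum (isozymes add capacity). Genes absent from `expr` contribute NA
# and are skipped inside min/sum where possible.
gpr_expression <- function(rule, expr) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  ev <- function(nd) {
    switch(nd$op,
      empty = NA_real_,
      gene  = if (nd$gene %in% names(expr)) expr[[nd$gene]] else NA_real_,
      and   = {
        v <- vapply(nd$children, ev, numeric(1))
        if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
      },
      or    = {
        v <- vapply(nd$children, ev, numeric(1))
        if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
      }
    )
  }
  ev(rule)
}
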