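# Tokenizer + recursive-descent parser for the MFQL dialect:
#
#   query    := "QUERYNAME" "=" ident ";" tolerance? define+ identify suchthat? report
#   tolerance:= "TOLERANCE" "=" number ("PPM"|"DA") ";"          (dialect extension)
#   define   := "DEFINE" ident "=" "'" sfpattern "'"
#               "WITH" "DBR" "=" "(" num "," num ")" "," "CHG" "=" int ";"
#   identify := "IDENTIFY" ident ("AND" ident)* "IN" context
#               ("," ident ("AND" ident)* "IN" context)* ";"
#   context  := MS1+ | MS1- | MS2+ | MS2-
#   suchthat := "SUCHTHAT" boolexpr ";"
#   report   := "REPORT" (ident "=" expr ";")+
#
# Expressions support + - * /, comparisons, AND/OR/NOT, membership
# (`expr IN (C16H31O2, ...)`), variable attributes .chemsc .mass .intensity
# .errppm, numeric literals and bare formula constants. `PR` aliases the
# query's MS1 variable.

MFQL_KEYWORDS <- c("QUERYNAME", "DEFINE", "WITH", "DBR", "CHG", "IDENTIFY",
                   "IN", "AND", "OR", "NOT", "SUCHTHAT", "REPORT",
                   "TOLERANCE", "PPM", "DA")
MFQL_ATTRS <- c("chemsc", "mass", "intensity", "errppm")

mfql_tokenize <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  toks <- list()
  push <- function(type, value, line, col) {
    toks[[length(toks) + 1]] <<- list(type = type, value = value,
                                      line = line, col = col)
  }
  for (ln in seq_along(lines)) {
    s <- sub("#.*$", "", lines[ln])
    i <- 1L
    while (i <= nchar(s)) {
      rest <- substr(s, i, nchar(s))
      ws <- regmatches(rest, regexpr("^\\s+", rest))
      if (length(ws) == 1) { i <- i + nchar(ws); next }
      m <- regmatches(rest, regexpr("^MS[12][+-]", rest))
      if (length(m) == 1) { push("CONTEXT", m, ln, i); i <- i + nchar(m); next }
      m <- regmatches(rest, regexpr("^'[^']*'", rest))
      if (length(m) == 1) {
        push("STRING", substr(m, 2, nchar(m) - 1), ln, i); i <- i + nchar(m); next
      }
      m <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]+)?", rest))
      if (length(m) == 1) { push("NUMBER", as.numeric(m), ln, i); i <- i + nchar(m); next }
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      if (length(m) == 1) {
        push(if (m %in% MFQL_KEYWORDS) m else "IDENT", m, ln, i)
        i <- i + nchar(m); next
      }
      m <- regmatches(rest, regexpr("^(==|<=|>=|!=|[-+*/=(),;.<>])", rest))
      if (length(m) == 1) { push("OP", m, ln, i); i <- i + nchar(m); next }
      stop(sprintf("MFQL lexical error at line %d, column %d: '%s'",
                   ln, i, substr(rest, 1, 10)), call. = FALSE)
    }
  }
  toks
}

is_formula_token <- function(x) {
  grepl("^([A-Z][a-z]?[0-9]*)+$", x) &&
    tryCatch({ as_composition(x); TRUE }, error = function(e) FALSE)
}

#' Parse an MFQL query
#'
#' Reads one query in the molecular-fragmentation query language dialect
#' (DEFINE / IDENTIFY / SUCHTHAT / REPORT) into an abstract syntax tree.
#' Variables used anywhere must be DEFINEd; exactly one variable is
#' identified in an MS1 context (it anchors each identification to one
#' precursor cluster, and may be referenced as `PR` in expressions); all
#' IDENTIFY contexts must share one polarity.
#'
#' @param text query text (character scalar or vector of lines).
#' @return An object of class `mfql_query`: `name`, `tolerance` (or NULL),
#'   `defines`, `identify`, `suchthat` (expression tree or NULL), `report`.
#' @examples
#' q <- read_mfql(mfql_example("pe_dda"))
#' q$name
#' @export
parse_mfql <- function(text) {
  toks <- mfql_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  fail <- function(msg, tok = peek()) {
    where <- if (is.null(tok)) "end of input" else {
      sprintf("line %d near '%s'", tok$line, tok$value)
    }
    stop("MFQL syntax error at ", where, ": ", msg, call. = FALSE)
  }
  take <- function(type = NULL, value = NULL) {
    tok <- peek()
    if (is.null(tok)) fail(paste("expected", type %||% value))
    if (!is.null(type) && tok$type != type) {
      fail(paste("expected", type), tok)
    }
    if (!is.null(value) && !identical(tok$value, value)) {
      fail(paste0("expected '", value, "'"), tok)
    }
    pos <<- pos + 1L
    tok
  }
  at <- function(type, value = NULL) {
    tok <- peek()
    !is.null(tok) && tok$type == type &&
      (is.null(value) || identical(tok$value, value))
  }

  take("QUERYNAME"); take("OP", "="); name <- take("IDENT")$value; take("OP", ";")

  tol <- NULL
  if (at("TOLERANCE")) {
    take("TOLERANCE"); take("OP", "=")
    v <- take("NUMBER")$value
    unit <- peek()
    if (at("PPM")) { take("PPM"); tol <- mass_tolerance(v, "ppm") }
    else if (at("DA")) { take("DA"); tol <- mass_tolerance(v, "mz") }
    else fail("expected PPM or DA")
    take("OP", ";")
  }

  defines <- list()
  while (at("DEFINE")) {
    take("DEFINE")
    var <- take("IDENT")$value
    if (var == "PR") fail("'PR' is reserved for the MS1 variable alias")
    take("OP", "=")
    pattern <- take("STRING")$value
    take("WITH"); take("DBR"); take("OP", "="); take("OP", "(")
    lo <- take("NUMBER")$value; take("OP", ",")
    hi <- take("NUMBER")$value; take("OP", ")")
    take("OP", ","); take("CHG"); take("OP", "=")
    sgn <- 1
    if (at("OP", "-")) { take("OP", "-"); sgn <- -1 }
    else if (at("OP", "+")) take("OP", "+")
    chg <- sgn * take("NUMBER")$value
    take("OP", ";")
    defines[[var]] <- tryCatch(
      parse_constraint(pattern, dbr = c(lo, hi), charge = chg),
      error = function(e) fail(paste0("malformed constraint for ", var, ": ",
                                      conditionMessage(e))))
  }
  if (length(defines) == 0) fail("query has no DEFINE clause")

  take("IDENTIFY")
  identify <- list()
  repeat {
    vars <- take("IDENT")$value
    while (at("AND")) { take("AND"); vars <- c(vars, take("IDENT")$value) }
    take("IN")
    ctx <- take("CONTEXT")$value
    for (v in vars) identify[[length(identify) + 1]] <- list(variable = v, context = ctx)
    if (at("OP", ",")) { take("OP", ","); next }
    break
  }
  take("OP", ";")

  known <- names(defines)
  for (cl in identify) {
    if (!cl$variable %in% known) {
      fail(paste0("IDENTIFY references undefined variable ", cl$variable))
    }
  }
  ms1_vars <- purrr::map_chr(purrr::keep(identify, ~ grepl("^MS1", .x$context)),
                             "variable")
  if (length(ms1_vars) != 1) {
    fail("this dialect requires exactly one variable identified in an MS1 context")
  }
  pols <- unique(substr(purrr::map_chr(identify, "context"), 4, 4))
  if (length(pols) != 1) fail("IDENTIFY contexts mix polarities")

  resolve_var <- function(v) if (v == "PR") ms1_vars else v

  # expression parser (precedence climbing)
  parse_or <- function() {
    e <- parse_and()
    while (at("OR")) { take("OR"); e <- list(type = "bin", op = "OR", l = e, r = parse_and()) }
    e
  }
  parse_and <- function() {
    e <- parse_not()
    while (at("AND")) { take("AND"); e <- list(type = "bin", op = "AND", l = e, r = parse_not()) }
    e
  }
  parse_not <- function() {
    if (at("NOT")) { take("NOT"); return(list(type = "not", e = parse_not())) }
    parse_cmp()
  }
  parse_cmp <- function() {
    e <- parse_add()
    if (at("OP") && peek()$value %in% c("==", "<", ">", "<=", ">=", "!=")) {
      op <- take("OP")$value
      return(list(type = "bin", op = op, l = e, r = parse_add()))
    }
    if (at("IN")) {
      take("IN"); take("OP", "(")
      set <- list()
      repeat {
        t <- take("IDENT")
        if (!is_formula_token(t$value)) fail("membership set expects formulas", t)
        set[[length(set) + 1]] <- as_composition(t$value)
        if (at("OP", ",")) { take("OP", ","); next }
        break
      }
      take("OP", ")")
      return(list(type = "in", e = e, set = set))
    }
    e
  }
  parse_add <- function() {
    e <- parse_mul()
    while (at("OP") && peek()$value %in% c("+", "-")) {
      op <- take("OP")$value
      e <- list(type = "bin", op = op, l = e, r = parse_mul())
    }
    e
  }
  parse_mul <- function() {
    e <- parse_primary()
    while (at("OP") && peek()$value %in% c("*", "/")) {
      op <- take("OP")$value
      e <- list(type = "bin", op = op, l = e, r = parse_primary())
    }
    e
  }
  parse_primary <- function() {
    if (at("NUMBER")) return(list(type = "num", v = take("NUMBER")$value))
    if (at("OP", "-")) { take("OP", "-"); return(list(type = "bin", op = "*",
                                                      l = list(type = "num", v = -1),
                                                      r = parse_primary())) }
    if (at("OP", "(")) { take("OP", "("); e <- parse_or(); take("OP", ")"); return(e) }
    tok <- take("IDENT")
    v <- tok$value
    if (v %in% c(known, "PR")) {
      take("OP", ".")
      attr <- take("IDENT")$value
      if (!attr %in% MFQL_ATTRS) {
        fail(paste0("unknown attribute '", attr, "' (expected one of ",
                    paste(MFQL_ATTRS, collapse = ", "), ")"), tok)
      }
      return(list(type = "var", var = resolve_var(v), attr = attr))
    }
    if (is_formula_token(v)) return(list(type = "comp", v = as_composition(v)))
    fail(paste0("undefined variable ", v), tok)
  }

  suchthat <- NULL
  if (at("SUCHTHAT")) {
    take("SUCHTHAT")
    if (!at("OP", ";")) suchthat <- parse_or()
    take("OP", ";")
  }

  take("REPORT")
  report <- list()
  repeat {
    if (at("REPORT")) take("REPORT") # the keyword may be repeated per column
    col <- take("IDENT")$value
    take("OP", "=")
    report[[col]] <- parse_or()
    take("OP", ";")
    if (!at("IDENT") && !at("REPORT")) break
  }
  if (length(report) == 0) fail("REPORT section is empty")
  if (!is.null(peek())) fail("unexpected trailing input")

  structure(list(name = name, tolerance = tol, defines = defines,
                 identify = identify, ms1_variable = ms1_vars,
                 polarity = if (pols == "+") 1L else -1L,
                 suchthat = suchthat, report = report),
            class = "mfql_query")
}

#' @export
print.mfql_query <- function(x, ...) {
  cat("<mfql_query> ", x$name, "\n", sep = "")
  for (v in names(x$defines)) cat("  DEFINE ", v, " = ", format(x$defines[[v]]), "\n", sep = "")
  cat("  IDENTIFY ", paste(purrr::map_chr(x$identify, ~ paste(.x$variable, "IN", .x$context)),
                           collapse = ", "), "\n", sep = "")
  cat("  SUCHTHAT ", if (is.null(x$suchthat)) "(none)" else "<expr>",
      "; REPORT ", paste(names(x$report), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an MFQL query file
#'
#' @param path path to a UTF-8 `.mfql` file holding one query.
#' @export
read_mfql <- function(path) {
  if (!file.exists(path)) stop("query file not found: ", path, call. = FALSE)
  parse_mfql(readLines(path, warn = FALSE))
}

#' Paths to the bundled example queries
#'
#' @param which one of `"pe_dda"`, `"pg_dda"` (negative-mode DDA/PIS
#'   queries), `"pe_nls"`, `"pg_nls"` (positive-mode neutral-loss queries);
#'   omit to list all.
#' @return File path(s) under the installed package.
#' @export
mfql_example <- function(which = NULL) {
  dir <- system.file("extdata", "mfql", package = "lipidquery")
  if (is.null(which)) return(list.files(dir, full.names = TRUE))
  f <- file.path(dir, paste0(which, ".mfql"))
  if (!file.exists(f)) stop("no bundled query '", which, "'", call. = FALSE)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
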