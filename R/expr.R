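# Expression layer of the model dialect: tokenizer, recursive-descent
# parser, deparser, variable analysis, and compilation to R language
# objects for vectorized evaluation.

# Function table: arity, and whether the call draws random numbers.
.FUNCTIONS <- list(
  exp      = list(arity = 1L, random = FALSE),
  log      = list(arity = 1L, random = FALSE),
  sqrt     = list(arity = 1L, random = FALSE),
  abs      = list(arity = 1L, random = FALSE),
  min      = list(arity = 2L, random = FALSE),
  max      = list(arity = 2L, random = FALSE),
  uniform  = list(arity = 0L, random = TRUE),
  gaussian = list(arity = 0L, random = TRUE),
  crossed  = list(arity = 2L, random = FALSE)
)

.IDENT_SEGMENT_RE <- "^[A-Za-z_$][A-Za-z0-9_]*$"

#' Split a dotted identifier into segments
#'
#' Identifiers in the model dialect are dotted paths such as `"Na.m"`;
#' the full stop delimits inclusion prefixes. `$`-prefixed segments are
#' reserved for built-in variables (`$t`, `$dt`, `$n`, `$p`, `$type`,
#' `$index`, `$init`).
#'
#' @param name Identifier string.
#' @return Character vector of segments.
#' @examples
#' identifier_segments("Na.m")
#' @export
identifier_segments <- function(name) {
  strsplit(name, ".", fixed = TRUE)[[1L]]
}

.is_valid_identifier <- function(name) {
  segs <- identifier_segments(name)
  length(segs) > 0L && all(grepl(.IDENT_SEGMENT_RE, segs))
}

# ---- tokenizer -----------------------------------------------------------

.tokenize_expr <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = i)
  num_re  <- "^([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?"
  id_re   <- "^[A-Za-z_$][A-Za-z0-9_$.]*"
  two_ops <- c("==", "!=", "<=", ">=", "&&", "||")
  one_ops <- c("+", "-", "*", "/", "^", "<", ">", "!", "(", ")", "[", "]", ",")
  while (i <= n) {
    rest <- substr(text, i, n)
    ch <- substr(rest, 1L, 1L)
    if (grepl("^\\s", ch)) { i <- i + 1L; next }
    m <- regmatches(rest, regexpr(num_re, rest))
    if (length(m) == 1L && nzchar(m)) {
      push("num", as.numeric(m)); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr(id_re, rest))
    if (length(m) == 1L && nzchar(m)) {
      push("name", m); i <- i + nchar(m); next
    }
    two <- substr(rest, 1L, 2L)
    if (two %in% two_ops) { push("op", two); i <- i + 2L; next }
    if (ch %in% one_ops)  { push("op", ch);  i <- i + 1L; next }
    stop(sprintf("unexpected character '%s' at position %d in expression: %s", ch, i, text),
         call. = FALSE)
  }
  tokens
}

# ---- parser --------------------------------------------------------------

# Precedence climbing; higher binds tighter. '^' is right-associative.
.BINARY_PREC <- c(
  "||" = 1, "&&" = 2,
  "==" = 3, "!=" = 3, "<" = 3, "<=" = 3, ">" = 3, ">=" = 3,
  "+" = 4, "-" = 4, "*" = 5, "/" = 5, "^" = 7
)

#' Parse an expression of the model dialect
#'
#' Supports numeric literals, dotted variable references, arithmetic
#' (`+ - * / ^`), comparisons, logical `&& || !` (also spelled
#' `and or not`), the fixed function set (`exp`, `log`, `sqrt`, `abs`,
#' `min`, `max`, `uniform()`, `gaussian()`, `crossed(x, theta)`), and --
#' only as the right-hand side of a `$type` equation -- a bracketed list
#' of part names such as `[Segment, GrowthCone]`.
#'
#' @param text Expression source text.
#' @param allow_typelist Permit a bracketed part-name list (used for
#'   `$type` right-hand sides).
#' @return An expression node: a list with a `kind` field (`"num"`,
#'   `"var"`, `"unary"`, `"binary"`, `"call"`, or `"typelist"`).
#' @export
parse_expression <- function(text, allow_typelist = FALSE) {
  tokens <- .tokenize_expr(text)
  if (length(tokens) == 0L) stop("empty expression", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens; st$i <- 1L; st$src <- text
  node <- if (allow_typelist && .peek_is(st, "op", "[")) .parse_typelist(st) else .parse_binary(st, 0)
  if (st$i <= length(st$tokens))
    stop(sprintf("trailing tokens in expression: %s", text), call. = FALSE)
  node
}

.peek <- function(st) if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
.peek_is <- function(st, type, value = NULL) {
  tk <- .peek(st)
  !is.null(tk) && tk$type == type && (is.null(value) || tk$value %in% value)
}
.advance <- function(st) { tk <- .peek(st); st$i <- st$i + 1L; tk }
.expect_op <- function(st, op) {
  tk <- .advance(st)
  if (is.null(tk) || tk$type != "op" || tk$value != op)
    stop(sprintf("expected '%s' in expression: %s", op, st$src), call. = FALSE)
  tk
}

.word_ops <- c(and = "&&", or = "||", not = "!")

.parse_binary <- function(st, min_prec) {
  left <- .parse_unary(st)
  repeat {
    tk <- .peek(st)
    if (is.null(tk)) break
    op <- if (tk$type == "op") tk$value
          else if (tk$type == "name" && tk$value %in% names(.word_ops)) .word_ops[[tk$value]]
          else NULL
    if (is.null(op) || !op %in% names(.BINARY_PREC)) break
    prec <- .BINARY_PREC[[op]]
    if (prec < min_prec) break
    .advance(st)
    next_min <- if (op == "^") prec else prec + 1
    right <- .parse_binary(st, next_min)
    left <- list(kind = "binary", op = op, a = left, b = right)
  }
  left
}

.parse_unary <- function(st) {
  tk <- .peek(st)
  if (!is.null(tk) && tk$type == "op" && tk$value %in% c("-", "+", "!")) {
    .advance(st)
    if (tk$value == "+") return(.parse_unary(st))
    return(list(kind = "unary", op = tk$value, a = .parse_unary(st)))
  }
  if (!is.null(tk) && tk$type == "name" && tk$value == "not") {
    .advance(st)
    return(list(kind = "unary", op = "!", a = .parse_unary(st)))
  }
  .parse_primary(st)
}

.parse_primary <- function(st) {
  tk <- .advance(st)
  if (is.null(tk)) stop(sprintf("unexpected end of expression: %s", st$src), call. = FALSE)
  if (tk$type == "num") return(list(kind = "num", value = tk$value))
  if (tk$type == "op" && tk$value == "(") {
    node <- .parse_binary(st, 0)
    .expect_op(st, ")")
    return(node)
  }
  if (tk$type == "name") {
    name <- tk$value
    if (.peek_is(st, "op", "(")) {
      .advance(st)
      fn <- .FUNCTIONS[[name]]
      if (is.null(fn))
        stop(sprintf("unknown function '%s' in expression: %s", name, st$src), call. = FALSE)
      args <- list()
      if (!.peek_is(st, "op", ")")) {
        repeat {
          args[[length(args) + 1L]] <- .parse_binary(st, 0)
          if (.peek_is(st, "op", ",")) { .advance(st); next }
          break
        }
      }
      .expect_op(st, ")")
      if (length(args) != fn$arity)
        stop(sprintf("function '%s' takes %d argument(s), got %d", name, fn$arity, length(args)),
             call. = FALSE)
      return(list(kind = "call", fn = name, args = args))
    }
    if (!.is_valid_identifier(name))
      stop(sprintf("invalid identifier '%s'", name), call. = FALSE)
    return(list(kind = "var", name = name))
  }
  stop(sprintf("unexpected token '%s' in expression: %s", tk$value, st$src), call. = FALSE)
}

.parse_typelist <- function(st) {
  .expect_op(st, "[")
  parts <- character(0)
  if (!.peek_is(st, "op", "]")) {
    repeat {
      tk <- .advance(st)
      if (is.null(tk) || tk$type != "name")
        stop("expected a part name inside [...] type list", call. = FALSE)
      parts <- c(parts, tk$value)
      if (.peek_is(st, "op", ",")) { .advance(st); next }
      break
    }
  }
  .expect_op(st, "]")
  list(kind = "typelist", parts = parts)
}

# ---- deparse -------------------------------------------------------------

#' Render an expression node back to dialect source text
#'
#' Inverse of [parse_expression()] up to whitespace and redundant
#' parentheses; used by the canonical serializer, so its output is stable.
#'
#' @param node Expression node.
#' @return Single string.
#' @export
deparse_expression <- function(node) .dep(node, 0)

.dep <- function(node, parent_prec) {
  out <- switch(node$kind,
    num = {
      v <- node$value
      if (v == floor(v) && abs(v) < 1e15) format(v, scientific = FALSE) else format(v, digits = 15)
    },
    var = node$name,
    unary = paste0(node$op, .dep(node$a, 6)),
    binary = {
      prec <- .BINARY_PREC[[node$op]]
      la <- .dep(node$a, if (node$op == "^") prec + 1 else prec)
      rb <- .dep(node$b, if (node$op == "^") prec else prec + 1)
      s <- paste(la, node$op, rb)
      if (prec < parent_prec) paste0("(", s, ")") else s
    },
    call = paste0(node$fn, "(", paste(vapply(node$args, .dep, "", 0), collapse = ", "), ")"),
    typelist = paste0("[", paste(node$parts, collapse = ", "), "]"),
    stop("unknown expression node kind: ", node$kind)
  )
  if (node$kind == "binary") out else out
}

# ---- analysis ------------------------------------------------------------

#' Variables referenced by an expression
#'
#' @param node Expression node.
#' @return Character vector of distinct dotted identifiers (excludes
#'   part names inside type lists).
#' @export
expression_vars <- function(node) {
  acc <- character(0)
  walk <- function(nd) {
    switch(nd$kind,
      var = acc <<- c(acc, nd$name),
      unary = walk(nd$a),
      binary = { walk(nd$a); walk(nd$b) },
      call = for (a in nd$args) walk(a),
      NULL)
  }
  walk(node)
  unique(acc)
}

.expression_has_random <- function(node) {
  found <- FALSE
  walk <- function(nd) {
    switch(nd$kind,
      call = {
        if (isTRUE(.FUNCTIONS[[nd$fn]]$random)) found <<- TRUE
        for (a in nd$args) walk(a)
      },
      unary = walk(nd$a),
      binary = { walk(nd$a); walk(nd$b) },
      NULL)
  }
  walk(node)
  found
}

# Rewrite variable names through `fn`, returning a new tree.
.expr_map_vars <- function(node, fn) {
  switch(node$kind,
    num = node,
    typelist = node,
    var = { node$name <- fn(node$name); node },
    unary = { node$a <- .expr_map_vars(node$a, fn); node },
    binary = {
      node$a <- .expr_map_vars(node$a, fn)
      node$b <- .expr_map_vars(node$b, fn)
      node
    },
    call = { node$args <- lapply(node$args, .expr_map_vars, fn = fn); node })
}

# ---- compilation to R ----------------------------------------------------

# Compile an expression node to an R language object evaluated in a
# population environment whose bindings are per-instance vectors.
# Logical operators map to their vectorized forms; min/max to pmin/pmax;
# uniform()/gaussian() to stream-drawing helpers `.rand_u`/`.rand_g`
# supplied by the evaluation environment; crossed(x, th) to an
# edge-trigger test against the previous step's values, which the
# environment exposes under `.prev.<name>` bindings.
.compile_expr <- function(node) {
  switch(node$kind,
    num = node$value,
    var = as.name(node$name),
    unary = if (node$op == "-") call("-", .compile_expr(node$a)) else call("!", .compile_expr(node$a)),
    binary = {
      op <- switch(node$op, "&&" = "&", "||" = "|", node$op)
      call(op, .compile_expr(node$a), .compile_expr(node$b))
    },
    call = switch(node$fn,
      uniform  = quote(.rand_u()),
      gaussian = quote(.rand_g()),
      min = call("pmin", .compile_expr(node$args[[1L]]), .compile_expr(node$args[[2L]])),
      max = call("pmax", .compile_expr(node$args[[1L]]), .compile_expr(node$args[[2L]])),
      crossed = {
        now <- .compile_expr(node$args[[1L]])
        prev <- .compile_expr(.expr_map_vars(node$args[[1L]], function(nm) paste0(".prev.", nm)))
        th <- .compile_expr(node$args[[2L]])
        call("&", call("<", prev, th), call(">=", now, th))
      },
      as.call(c(list(as.name(node$fn)), lapply(node$args, .compile_expr)))),
    typelist = stop("a [..] type list cannot appear inside an expression", call. = FALSE)
  )
}

# Variables whose previous-step values are needed (referenced inside
# crossed()).
.expr_prev_vars <- function(node) {
  acc <- character(0)
  walk <- function(nd) {
    switch(nd$kind,
      call = {
        if (nd$fn == "crossed") acc <<- c(acc, expression_vars(nd$args[[1L]]))
        for (a in nd$args) walk(a)
      },
      unary = walk(nd$a),
      binary = { walk(nd$a); walk(nd$b) },
      NULL)
  }
  walk(node)
  unique(acc)
}
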