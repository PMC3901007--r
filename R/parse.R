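# Parser for the part-equation model dialect.
#
# The dialect is line-oriented: a `part` header opens a block, indented
# lines inside the block declare inheritance (`: Parent` on the header),
# inclusion (`include alias = Part`), connection endpoint bindings
# (`connect a = Part, b = Part`), equations (`target[''] = expr [@ cond]`),
# metadata (`$meta key = value`) and references (`$ref key`).  Comments
# run from `//` to end of line.  A top-level `model Name` line marks the
# repository's entry part.

#' Construct an equation object
#'
#' @param target Dotted identifier being defined.
#' @param order Derivative order (number of primes on the target, 0--2).
#' @param expr Expression node (see [parse_expression()]).
#' @param condition Optional expression node; `NULL` means always active.
#' @param line Source line number, kept for diagnostics.
#' @return An object of class `"mdl_equation"`.
#' @export
new_equation <- function(target, order, expr, condition = NULL, line = NA_integer_) {
  stopifnot(.is_valid_identifier(target), order >= 0L, order <= 2L)
  structure(list(target = target, order = as.integer(order), expr = expr,
                 condition = condition, line = line),
            class = "mdl_equation")
}

#' Parse a single equation line
#'
#' The target may carry one or two prime marks (`'`) denoting first or
#' second time derivatives; an optional `@` clause gives the activation
#' condition.  `x = 5` is an order-0 equation; `V' = -V / tau` an
#' order-1 differential equation; `g = g + w @ crossed(A.V, theta)` an
#' event-triggered assignment.
#'
#' @param line Equation source text.
#' @param lineno Line number recorded for diagnostics.
#' @return An `"mdl_equation"` object.
#' @export
parse_equation <- function(line, lineno = NA_integer_) {
  line <- .strip_comment(line)
  m <- regexec("^\\s*([A-Za-z_$][A-Za-z0-9_$.]*)('{0,3})\\s*=\\s*(.*)$", line)
  g <- regmatches(line, m)[[1L]]
  if (length(g) == 0L)
    stop(sprintf("line %s: not an equation: %s", lineno, line), call. = FALSE)
  target <- g[2L]
  order <- nchar(g[3L])
  if (order > 2L)
    stop(sprintf("line %s: at most two primes are supported: %s", lineno, line), call. = FALSE)
  if (!.is_valid_identifier(target))
    stop(sprintf("line %s: invalid identifier '%s'", lineno, target), call. = FALSE)
  rhs <- g[4L]
  if (!nzchar(trimws(rhs)))
    stop(sprintf("line %s: empty right-hand side", lineno), call. = FALSE)
  at <- .split_condition(rhs)
  is_type <- identical(utils::tail(identifier_segments(target), 1L), "$type")
  expr <- parse_expression(at$expr, allow_typelist = is_type)
  cond <- if (is.null(at$cond)) NULL else parse_expression(at$cond)
  new_equation(target, order, expr, cond, lineno)
}

# Split "expr @ cond" at the first top-level '@'.
.split_condition <- function(rhs) {
  pos <- regexpr("@", rhs, fixed = TRUE)
  if (pos < 0L) return(list(expr = trimws(rhs), cond = NULL))
  list(expr = trimws(substr(rhs, 1L, pos - 1L)),
       cond = trimws(substr(rhs, pos + 1L, nchar(rhs))))
}

.strip_comment <- function(line) sub("//.*$", "", line)

#' Parse a metadata value
#'
#' Recognizes the measurement notation `<number> [± <number>] [unit]`
#' (the ASCII spelling `+/-` is also accepted), e.g.
#' `"12481.9 ± 2998.9 um"`.  Anything else is kept as plain text.
#' The raw input is always preserved verbatim.
#'
#' @param raw Metadata value text.
#' @return An object of class `"metadata_value"` with fields `raw`,
#'   `mean`, `uncertainty`, `unit` (the last three `NA` when absent).
#' @export
parse_metadata_value <- function(raw) {
  raw <- as.character(raw)
  num <- "[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?"
  pat <- paste0("^\\s*(", num, ")\\s*(?:(?:±|\\+/-)\\s*(", num, "))?\\s*([A-Za-z_%][A-Za-z0-9_/%^-]*)?\\s*$")
  m <- regmatches(raw, regexec(pat, raw))[[1L]]
  out <- list(raw = raw, mean = NA_real_, uncertainty = NA_real_, unit = NA_character_)
  if (length(m) > 0L) {
    out$mean <- as.numeric(m[2L])
    if (nzchar(m[5L])) out$uncertainty <- as.numeric(m[5L])
    if (nzchar(m[8L])) out$unit <- m[8L]
  }
  structure(out, class = "metadata_value")
}

#' @export
format.metadata_value <- function(x, ...) x$raw

#' @export
print.metadata_value <- function(x, ...) {
  cat(x$raw, "\n")
  invisible(x)
}

# ---- repository ----------------------------------------------------------

.new_part <- function(name, parents = character(0), line = NA_integer_) {
  structure(list(name = name, parents = parents,
                 includes = character(0),   # named: alias -> part name
                 connect = character(0),    # named: alias -> part name (0 or 2)
                 equations = list(), metadata = list(), refs = character(0),
                 line = line),
            class = "mdl_part")
}

.new_repository <- function(parts = list(), model_entry = NULL) {
  structure(list(parts = parts, model_entry = model_entry), class = "part_repository")
}

#' @export
print.part_repository <- function(x, ...) {
  cat(sprintf("<part repository: %d part(s)%s>\n", length(x$parts),
              if (is.null(x$model_entry)) "" else paste0(", model entry '", x$model_entry, "'")))
  for (p in x$parts)
    cat(sprintf("  %s: %d equation(s)\n", p$name, length(p$equations)))
  invisible(x)
}

#' Parse model-dialect source text
#'
#' @param text Model source as a single string or a character vector of
#'   lines.
#' @return A `"part_repository"` object.
#' @seealso [parse_model_file()] to read from a file,
#'   [serialize_repository()] for the inverse.
#' @export
parse_model_text <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  repo <- .new_repository()
  current <- NULL
  flush_part <- function() {
    if (is.null(current)) return()
    if (!is.null(repo$parts[[current$name]]))
      stop(sprintf("duplicate part name '%s'", current$name), call. = FALSE)
    repo$parts[[current$name]] <<- current
  }
  for (i in seq_along(lines)) {
    raw <- .strip_comment(lines[[i]])
    if (!nzchar(trimws(raw))) next
    indented <- grepl("^\\s", raw)
    line <- trimws(raw)
    if (!indented) {
      hm <- regmatches(line, regexec("^part\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*(?::\\s*(.*))?$", line))[[1L]]
      if (length(hm) > 0L) {
        flush_part()
        parents <- character(0)
        if (nzchar(hm[3L])) {
          parents <- trimws(strsplit(hm[3L], ",", fixed = TRUE)[[1L]])
          bad <- parents[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", parents)]
          if (length(bad))
            stop(sprintf("line %d: invalid parent name '%s'", i, bad[[1L]]), call. = FALSE)
        }
        current <- .new_part(hm[2L], parents, i)
        next
      }
      mm <- regmatches(line, regexec("^model\\s+([A-Za-z_][A-Za-z0-9_]*)$", line))[[1L]]
      if (length(mm) > 0L) {
        flush_part(); current <- NULL
        repo$model_entry <- mm[2L]
        next
      }
      stop(sprintf("line %d: expected 'part' or 'model' header: %s", i, line), call. = FALSE)
    }
    if (is.null(current))
      stop(sprintf("line %d: statement outside any part block: %s", i, line), call. = FALSE)
    current <- .parse_part_statement(current, line, i)
  }
  flush_part()
  repo
}

#' Parse a model-dialect file
#'
#' @param path Path to a dialect source file (UTF-8 text).
#' @return A `"part_repository"` object.
#' @export
parse_model_file <- function(path) {
  parse_model_text(readLines(path, encoding = "UTF-8", warn = FALSE))
}

.parse_part_statement <- function(part, line, lineno) {
  im <- regmatches(line, regexec(
    "^include\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([A-Za-z_][A-Za-z0-9_]*)$", line))[[1L]]
  if (length(im) > 0L) {
    alias <- im[2L]
    if (alias %in% names(part$includes) || alias %in% names(part$connect))
      stop(sprintf("line %d: duplicate alias '%s' in part '%s'", lineno, alias, part$name),
           call. = FALSE)
    part$includes[[alias]] <- im[3L]
    return(part)
  }
  cm <- regmatches(line, regexec(
    paste0("^connect\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*,",
           "\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([A-Za-z_][A-Za-z0-9_]*)$"), line))[[1L]]
  if (length(cm) > 0L) {
    if (length(part$connect))
      stop(sprintf("line %d: part '%s' already has a connect declaration", lineno, part$name),
           call. = FALSE)
    if (cm[2L] == cm[4L])
      stop(sprintf("line %d: connection endpoint aliases must differ", lineno), call. = FALSE)
    part$connect <- stats::setNames(c(cm[3L], cm[5L]), c(cm[2L], cm[4L]))
    return(part)
  }
  mm <- regmatches(line, regexec("^\\$meta\\s+([A-Za-z_][A-Za-z0-9_ .-]*?)\\s*=\\s*(.*)$", line))[[1L]]
  if (length(mm) > 0L) {
    part$metadata[[mm[2L]]] <- parse_metadata_value(mm[3L])
    return(part)
  }
  rm_ <- regmatches(line, regexec("^\\$ref\\s+(\\S+)$", line))[[1L]]
  if (length(rm_) > 0L) {
    part$refs <- union(part$refs, rm_[2L])
    return(part)
  }
  eq <- parse_equation(line, lineno)
  if (is.null(eq$condition)) {
    dup <- vapply(part$equations, function(e)
      is.null(e$condition) && e$target == eq$target && e$order == eq$order, logical(1))
    if (any(dup))
      stop(sprintf("line %d: duplicate unconditioned equation for '%s'%s in part '%s'",
                   lineno, eq$target, strrep("'", eq$order), part$name), call. = FALSE)
  }
  part$equations[[length(part$equations) + 1L]] <- eq
  part
}

# ---- serialization -------------------------------------------------------

.format_equation <- function(eq) {
  paste0(eq$target, strrep("'", eq$order), " = ", deparse_expression(eq$expr),
         if (!is.null(eq$condition)) paste0(" @ ", deparse_expression(eq$condition)) else "")
}

#' Serialize a repository to canonical dialect text
#'
#' Parts are emitted alphabetically, equations ordered by target, order,
#' and condition text; `parse_model_text(serialize_repository(r))`
#' reproduces `r` up to source-location bookkeeping, and the canonical
#' ordering makes the output suitable for content hashing.
#'
#' @param repo A `"part_repository"`.
#' @return A single string of dialect source (empty for an empty
#'   repository).
#' @export
serialize_repository <- function(repo) {
  stopifnot(inherits(repo, "part_repository"))
  out <- character(0)
  if (!is.null(repo$model_entry)) out <- c(out, paste("model", repo$model_entry))
  for (nm in sort(names(repo$parts))) {
    p <- repo$parts[[nm]]
    header <- paste0("part ", p$name,
                     if (length(p$parents)) paste0(" : ", paste(p$parents, collapse = ", ")) else "")
    out <- c(out, header)
    if (length(p$connect))
      out <- c(out, paste0("  connect ", names(p$connect)[1L], " = ", p$connect[[1L]],
                           ", ", names(p$connect)[2L], " = ", p$connect[[2L]]))
    for (al in sort(names(p$includes)))
      out <- c(out, paste0("  include ", al, " = ", p$includes[[al]]))
    eqs <- p$equations
    if (length(eqs)) {
      key <- vapply(eqs, function(e)
        paste(e$target, e$order, if (is.null(e$condition)) "" else deparse_expression(e$condition)),
        "")
      eqs <- eqs[order(key)]
      out <- c(out, vapply(eqs, function(e) paste0("  ", .format_equation(e)), ""))
    }
    for (k in sort(names(p$metadata)))
      out <- c(out, paste0("  $meta ", k, " = ", p$metadata[[k]]$raw))
    for (r in sort(p$refs)) out <- c(out, paste0("  $ref ", r))
  }
  if (length(out) == 0L) "" else paste0(paste(out, collapse = "\n"), "\n")
}

# ---- validation ----------------------------------------------------------

#' Validate a repository
#'
#' Checks that parent, include, and connect references resolve, that the
#' inheritance and inclusion graphs are acyclic, that connection parts
#' bind exactly two endpoints, and that aliases do not collide with
#' local variable names.
#'
#' @param repo A `"part_repository"`.
#' @return Character vector of diagnostics; empty when the repository is
#'   valid.
#' @export
validate_repository <- function(repo) {
  stopifnot(inherits(repo, "part_repository"))
  diags <- character(0)
  say <- function(...) diags <<- c(diags, sprintf(...))
  names_ <- names(repo$parts)
  for (p in repo$parts) {
    for (par in p$parents)
      if (!par %in% names_) say("part '%s': unknown parent '%s'", p$name, par)
    for (al in names(p$includes))
      if (!p$includes[[al]] %in% names_)
        say("part '%s': include '%s' refers to unknown part '%s'", p$name, al, p$includes[[al]])
    for (al in names(p$connect))
      if (!p$connect[[al]] %in% names_)
        say("part '%s': connect endpoint '%s' refers to unknown part '%s'",
            p$name, al, p$connect[[al]])
    if (!length(p$connect) %in% c(0L, 2L))
      say("part '%s': connection parts must bind exactly 2 endpoints", p$name)
    locals <- unique(vapply(p$equations, function(e) identifier_segments(e$target)[[1L]], ""))
    clash <- intersect(c(names(p$includes), names(p$connect)), locals)
    for (al in clash) {
      # a prefixed override (alias.x = ...) is the mechanism, not a clash;
      # only a bare equation whose whole target equals the alias collides
      bare <- any(vapply(p$equations, function(e) e$target == al, logical(1)))
      if (bare) say("part '%s': alias '%s' collides with a local variable", p$name, al)
    }
  }
  if (!is.null(repo$model_entry) && !repo$model_entry %in% names_)
    say("model entry '%s' is not a part in the repository", repo$model_entry)
  diags <- c(diags, .cycle_diagnostics(repo, "parents", "inheritance"))
  diags <- c(diags, .cycle_diagnostics(repo, "includes", "inclusion"))
  diags
}

.cycle_diagnostics <- function(repo, field, label) {
  diags <- character(0)
  color <- stats::setNames(rep(0L, length(repo$parts)), names(repo$parts))  # 0 new, 1 open, 2 done
  visit <- function(nm, trail) {
    if (!nm %in% names(color)) return()
    if (color[[nm]] == 1L) {
      diags <<- c(diags, sprintf("%s cycle involving part '%s' (via %s)",
                                 label, nm, paste(trail, collapse = " -> ")))
      return()
    }
    if (color[[nm]] == 2L) return()
    color[[nm]] <<- 1L
    nxt <- repo$parts[[nm]][[field]]
    for (target in unname(nxt)) visit(target, c(trail, target))
    color[[nm]] <<- 2L
  }
  for (nm in names(repo$parts)) visit(nm, nm)
  unique(diags)
}
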