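# Composition: resolve inheritance (is-a) and inclusion (has-a) into a
# flat equation set per part, then compile a model part into population
# and connection templates.
#
# Hiding rules: a definition in the child hides a parent's definition of
# the same (target, order, condition); among multiple parents the
# leftmost-listed wins.  Included equations are prefixed with their
# alias; a prefixed definition in the includer hides the included one,
# and prefixes compose through arbitrarily deep nesting.  References to
# names the included part defines are rewritten under the prefix;
# references it leaves free (including `$`-builtins) bind in the
# including scope.

.eq_key <- function(eq) {
  paste(eq$target, eq$order,
        if (is.null(eq$condition)) "" else deparse_expression(eq$condition),
        sep = "\r")
}

#' Flatten a part: resolve inheritance and inclusion
#'
#' Produces the complete equation set a part contributes as a template:
#' parent equations merged (leftmost parent precedence, child hides
#' parents), included parts flattened recursively and namespaced under
#' their alias, and the part's own definitions applied last.
#'
#' @param repo A `"part_repository"`.
#' @param name Part name to flatten.
#' @return An object of class `"flattened_part"` with fields `origin`,
#'   `equations` (named by target/order/condition key, in definition
#'   order), `metadata`, `refs`, `connect` (endpoint bindings),
#'   `includes` (effective alias map), `provenance` (defining part per
#'   equation key), and `defined` (names this part defines).
#' @export
flatten_part <- function(repo, name) {
  stopifnot(inherits(repo, "part_repository"))
  .flatten_part(repo, name, character(0))
}

#' @rdname flatten_part
#' @export
resolve_inheritance <- function(repo, name) flatten_part(repo, name)

#' @rdname flatten_part
#' @export
resolve_inclusion <- function(repo, name) flatten_part(repo, name)

.flatten_part <- function(repo, name, visiting) {
  if (name %in% visiting)
    stop(sprintf("cycle in part composition involving '%s'", name), call. = FALSE)
  p <- repo$parts[[name]]
  if (is.null(p)) stop(sprintf("unknown part '%s'", name), call. = FALSE)
  visiting <- c(visiting, name)

  equations <- list()   # key -> equation
  provenance <- character(0)
  metadata <- list()
  refs <- character(0)
  connect <- character(0)
  includes <- character(0)

  put <- function(eq, from, override) {
    key <- .eq_key(eq)
    if (!override && !is.null(equations[[key]])) return()
    equations[[key]] <<- eq
    provenance[[key]] <<- from
  }

  # layer 1: parents, leftmost wins
  for (parent in p$parents) {
    fp <- .flatten_part(repo, parent, visiting)
    for (key in names(fp$equations))
      if (is.null(equations[[key]])) {
        equations[[key]] <- fp$equations[[key]]
        provenance[[key]] <- fp$provenance[[key]]
      }
    for (k in names(fp$metadata)) if (is.null(metadata[[k]])) metadata[[k]] <- fp$metadata[[k]]
    refs <- union(refs, fp$refs)
    if (!length(connect)) connect <- fp$connect
    for (al in names(fp$includes)) if (!al %in% names(includes)) includes[[al]] <- fp$includes[[al]]
  }

  # layer 2: includes, namespaced under alias; override parents
  own_includes <- p$includes
  for (al in names(own_includes)) includes[[al]] <- own_includes[[al]]
  for (al in names(own_includes)) {
    fi <- .flatten_part(repo, own_includes[[al]], visiting)
    rename <- function(nm) {
      if (nm %in% fi$defined) paste0(al, ".", nm) else nm
    }
    for (key in names(fi$equations)) {
      eq <- fi$equations[[key]]
      eq$target <- paste0(al, ".", eq$target)
      eq$expr <- .expr_map_vars(eq$expr, rename)
      if (!is.null(eq$condition)) eq$condition <- .expr_map_vars(eq$condition, rename)
      put(eq, fi$provenance[[key]] %||% fi$origin, override = TRUE)
    }
    for (k in names(fi$metadata)) metadata[[paste0(al, ".", k)]] <- fi$metadata[[k]]
    refs <- union(refs, fi$refs)
  }

  # layer 3: the part's own definitions hide everything
  for (eq in p$equations) put(eq, name, override = TRUE)
  for (k in names(p$metadata)) metadata[[k]] <- p$metadata[[k]]
  refs <- union(refs, p$refs)
  if (length(p$connect)) connect <- p$connect

  defined <- unique(vapply(equations, function(e) e$target, ""))
  structure(list(origin = name, equations = equations, provenance = provenance,
                 metadata = metadata, refs = refs, connect = connect,
                 includes = includes, defined = defined),
            class = "flattened_part")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up an equation in a flattened part or template
#'
#' @param fp A `"flattened_part"` (or a compiled template).
#' @param target Dotted identifier.
#' @param order Derivative order.
#' @return The matching unconditioned `"mdl_equation"`, or `NULL`.
#' @export
get_equation <- function(fp, target, order = 0L) {
  for (eq in fp$equations)
    if (eq$target == target && eq$order == order && is.null(eq$condition)) return(eq)
  NULL
}

# ---- model compilation ---------------------------------------------------

#' Compile a model part into population and connection templates
#'
#' Every part the model includes becomes either a population template
#' (ordinary part; initial size from its `$n` equation, default 1) or a
#' connection template (a part with a `connect` declaration), with
#' model-level prefixed equations already folded in as overrides.
#' Connection endpoints are bound to sibling populations either
#' explicitly (a model equation `<connAlias>.<endpoint> = <popPrefix>`)
#' or by matching the endpoint's declared part name against the
#' populations' parts (including their ancestors).
#'
#' @param repo A `"part_repository"`.
#' @param model Name of the model part (defaults to the repository's
#'   model entry).
#' @return An object of class `"compiled_model"` with fields
#'   `model_name`, `populations`, `connections`, `globals`, and
#'   `content_hash`.
#' @export
flatten_model <- function(repo, model = repo$model_entry) {
  if (is.null(model)) stop("no model part given and repository has no model entry", call. = FALSE)
  fm <- flatten_part(repo, model)
  aliases <- names(fm$includes)

  strip_prefix <- function(al) {
    pre <- paste0(al, ".")
    eqs <- list()
    for (eq in fm$equations) {
      if (startsWith(eq$target, pre)) {
        eq$target <- substring(eq$target, nchar(pre) + 1L)
        eq$expr <- .expr_map_vars(eq$expr, function(nm)
          if (startsWith(nm, pre)) substring(nm, nchar(pre) + 1L) else nm)
        if (!is.null(eq$condition))
          eq$condition <- .expr_map_vars(eq$condition, function(nm)
            if (startsWith(nm, pre)) substring(nm, nchar(pre) + 1L) else nm)
        eqs[[.eq_key(eq)]] <- eq
      }
    }
    eqs
  }

  populations <- list()
  connections <- list()
  for (al in aliases) {
    part_name <- fm$includes[[al]]
    fp <- flatten_part(repo, part_name)
    template <- fp
    template$equations <- strip_prefix(al)
    entry <- list(prefix = al, part = part_name, template = template,
                  connect = fp$connect)
    if (length(fp$connect) == 2L) connections[[al]] <- entry else populations[[al]] <- entry
  }

  # model-scope equations not under any include alias become globals
  globals <- list()
  for (eq in fm$equations) {
    first <- identifier_segments(eq$target)[[1L]]
    if (!first %in% aliases) globals[[.eq_key(eq)]] <- eq
  }

  # resolve connection endpoints to population prefixes
  ancestors <- function(pn) {
    out <- pn
    queue <- pn
    while (length(queue)) {
      q <- queue[[1L]]; queue <- queue[-1L]
      ps <- repo$parts[[q]]$parents
      ps <- setdiff(ps, out)
      out <- c(out, ps); queue <- c(queue, ps)
    }
    out
  }
  for (al in names(connections)) {
    conn <- connections[[al]]
    endpoints <- character(0)
    for (ep in names(conn$connect)) {
      bound_part <- conn$connect[[ep]]
      explicit <- get_equation(conn$template, ep, 0L)
      if (!is.null(explicit) && explicit$expr$kind == "var" &&
          explicit$expr$name %in% names(populations)) {
        endpoints[[ep]] <- explicit$expr$name
        next
      }
      hits <- names(populations)[vapply(populations, function(pp)
        bound_part %in% ancestors(pp$part), logical(1))]
      if (length(hits) == 0L)
        stop(sprintf("connection '%s': endpoint '%s' (part '%s') matches no population",
                     al, ep, bound_part), call. = FALSE)
      if (length(hits) > 1L)
        stop(sprintf(paste0("connection '%s': endpoint '%s' (part '%s') is ambiguous among ",
                            "populations %s; bind explicitly with '%s.%s = <population>'"),
                     al, ep, bound_part, paste(hits, collapse = ", "), al, ep), call. = FALSE)
      endpoints[[ep]] <- hits[[1L]]
    }
    connections[[al]]$endpoints <- endpoints
  }

  cm <- structure(list(model_name = model, populations = populations,
                       connections = connections, globals = globals,
                       content_hash = NA_character_),
                  class = "compiled_model")
  cm$content_hash <- content_hash(cm)
  cm
}

#' @export
print.compiled_model <- function(x, ...) {
  cat(sprintf("<compiled model '%s': %d population(s), %d connection template(s)>\n",
              x$model_name, length(x$populations), length(x$connections)))
  cat("  hash:", substr(x$content_hash, 1, 12), "\n")
  invisible(x)
}

# Canonical text rendering of a compiled model, the input to the hash.
.render_compiled <- function(cm) {
  out <- c(paste("model", cm$model_name))
  render_tmpl <- function(entry, kind) {
    eqs <- entry$template$equations
    txt <- sort(vapply(eqs, .format_equation, ""))
    hdr <- paste0(kind, " ", entry$prefix, " ", entry$part,
                  if (kind == "connection")
                    paste0(" [", paste(names(entry$endpoints), "=", entry$endpoints, collapse = ", "), "]")
                  else "")
    c(hdr, paste0("  ", txt))
  }
  for (al in sort(names(cm$populations)))
    out <- c(out, render_tmpl(cm$populations[[al]], "population"))
  for (al in sort(names(cm$connections)))
    out <- c(out, render_tmpl(cm$connections[[al]], "connection"))
  if (length(cm$globals))
    out <- c(out, "globals", paste0("  ", sort(vapply(cm$globals, .format_equation, ""))))
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Content hash of a compiled model
#'
#' SHA-256 digest of the model's canonical text rendering: stable under
#' re-serialization and equation reordering, changed by any change to a
#' constant, equation, or wiring.
#'
#' @param cm A `"compiled_model"`.
#' @return 64-character lowercase hex digest.
#' @export
content_hash <- function(cm) {
  stopifnot(inherits(cm, "compiled_model"))
  .sha256_hex(.render_compiled(cm))
}

#' Override a constant in a compiled model
#'
#' Replaces the right-hand side of an order-0, unconditioned equation --
#' addressed by a dotted path whose first segment is a population or
#' connection prefix, or a model-scope global -- with a numeric literal.
#' The input model is left untouched; the returned model has a new
#' content hash.  Differential-equation targets are refused.
#'
#' @param cm A `"compiled_model"`.
#' @param path Dotted path, e.g. `"comp.Na.gbar"` or `"Esyn.w"`.
#' @param value Numeric replacement.
#' @return A new `"compiled_model"`.
#' @export
override_parameter <- function(cm, path, value) {
  stopifnot(inherits(cm, "compiled_model"), is.numeric(value), length(value) == 1L)
  segs <- identifier_segments(path)
  first <- segs[[1L]]
  lit <- list(kind = "num", value = as.numeric(value))
  replace_in <- function(tmpl, target) {
    hit <- FALSE
    for (key in names(tmpl$equations)) {
      eq <- tmpl$equations[[key]]
      if (eq$target == target && is.null(eq$condition)) {
        if (eq$order > 0L)
          stop(sprintf("path '%s' targets a differential equation; only constants can be overridden",
                       path), call. = FALSE)
        eq$expr <- lit
        tmpl$equations[[key]] <- eq
        hit <- TRUE
      }
    }
    if (!hit) stop(sprintf("path '%s' does not resolve to an equation", path), call. = FALSE)
    tmpl
  }
  if (first %in% names(cm$populations)) {
    target <- paste(segs[-1L], collapse = ".")
    cm$populations[[first]]$template <- replace_in(cm$populations[[first]]$template, target)
  } else if (first %in% names(cm$connections)) {
    target <- paste(segs[-1L], collapse = ".")
    cm$connections[[first]]$template <- replace_in(cm$connections[[first]]$template, target)
  } else {
    hit <- FALSE
    for (key in names(cm$globals)) {
      eq <- cm$globals[[key]]
      if (eq$target == path && is.null(eq$condition)) {
        if (eq$order > 0L)
          stop(sprintf("path '%s' targets a differential equation", path), call. = FALSE)
        eq$expr <- lit
        cm$globals[[key]] <- eq
        hit <- TRUE
      }
    }
    if (!hit)
      stop(sprintf("path '%s' does not resolve to a constant in the model", path), call. = FALSE)
  }
  cm$content_hash <- content_hash(cm)
  cm
}
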