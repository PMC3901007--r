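# Compile population and connection templates into runtime plans:
# equations classified by role, expressions compiled to R language
# objects, algebraic (order-0 unconditioned) equations topologically
# ordered, and the variables that need previous-step values (for
# crossed()) collected.

.is_init_cond <- function(cond) {
  !is.null(cond) && cond$kind == "var" && cond$name == "$init"
}

.compile_template <- function(entry, kind) {
  tmpl <- entry$template
  ep_aliases <- if (kind == "conn") names(entry$endpoints) else character(0)

  plan <- list(prefix = entry$prefix, part = entry$part, kind = kind,
               deriv = list(),      # target -> list(expr, order)
               aux_det = list(),    # target -> expr (topologically ordered below)
               aux_rand = list(),   # target -> expr
               init = list(),       # list(target, order, expr)
               events = list(),     # list(target, cond, expr)
               type_eqs = list(),   # list(parts, cond)
               ep_deriv = list(),   # list(alias, var, expr)        (conn)
               ep_accum = list(),   # list(alias, var, expr)        (conn)
               ep_events = list(),  # list(alias, var, cond, expr)  (conn)
               n_expr = NULL, p_expr = NULL, p_random = FALSE,
               endpoints = if (kind == "conn") entry$endpoints else NULL,
               prev_local = character(0),  # own vars needing prev values
               prev_gather = character(0), # endpoint-prefixed names needing prev
               gather = character(0),      # endpoint-prefixed names referenced
               input_vars = character(0),  # zeroed-per-stage accumulator inputs
               vars = character(0))

  note_prev <- function(nodes) {
    for (nd in nodes) {
      if (is.null(nd)) next
      pv <- .expr_prev_vars(nd)
      ep <- pv[vapply(pv, function(v) identifier_segments(v)[[1L]] %in% ep_aliases, logical(1))]
      plan$prev_gather <<- union(plan$prev_gather, ep)
      plan$prev_local <<- union(plan$prev_local, setdiff(pv, ep))
    }
  }
  note_gather <- function(nodes) {
    if (kind != "conn") return()
    for (nd in nodes) {
      if (is.null(nd)) next
      vars <- expression_vars(nd)
      ep <- vars[vapply(vars, function(v) identifier_segments(v)[[1L]] %in% ep_aliases, logical(1))]
      plan$gather <<- union(plan$gather, ep)
    }
  }

  for (eq in tmpl$equations) {
    tgt <- eq$target
    segs <- identifier_segments(tgt)
    is_ep <- length(ep_aliases) > 0L && segs[[1L]] %in% ep_aliases
    cond <- eq$condition
    note_prev(list(eq$expr, cond))
    note_gather(list(eq$expr, cond))

    if (tgt == "$n" && kind == "pop" && eq$order == 0L && is.null(cond)) {
      plan$n_expr <- .compile_expr(eq$expr)
      next
    }
    if (tgt == "$p" && kind == "conn" && eq$order == 0L) {
      if (!is.null(cond))
        stop(sprintf("group '%s': $p cannot carry a condition", entry$prefix), call. = FALSE)
      plan$p_expr <- .compile_expr(eq$expr)
      plan$p_random <- .expression_has_random(eq$expr)
      next
    }
    if (identical(segs[[length(segs)]], "$type")) {
      if (eq$expr$kind != "typelist")
        stop(sprintf("group '%s': $type must be assigned a [..] part list", entry$prefix),
             call. = FALSE)
      plan$type_eqs[[length(plan$type_eqs) + 1L]] <-
        list(parts = eq$expr$parts,
             cond = if (is.null(cond)) TRUE else .compile_expr(cond))
      next
    }
    if (.is_init_cond(cond)) {
      if (is_ep)
        stop(sprintf("group '%s': endpoint variables cannot be initialized from a connection",
                     entry$prefix), call. = FALSE)
      plan$init[[length(plan$init) + 1L]] <-
        list(target = tgt, order = eq$order, expr = .compile_expr(eq$expr),
             random = .expression_has_random(eq$expr))
      next
    }
    if (eq$order >= 1L) {
      if (!is.null(cond))
        stop(sprintf("group '%s': conditioned differential equations are not supported ('%s')",
                     entry$prefix, tgt), call. = FALSE)
      if (is_ep) {
        plan$ep_deriv[[length(plan$ep_deriv) + 1L]] <-
          list(alias = segs[[1L]], var = paste(segs[-1L], collapse = "."),
               order = eq$order, expr = .compile_expr(eq$expr))
      } else {
        plan$deriv[[tgt]] <- list(expr = .compile_expr(eq$expr), order = eq$order)
      }
      next
    }
    # order 0
    if (is.null(cond)) {
      if (is_ep) {
        plan$ep_accum[[length(plan$ep_accum) + 1L]] <-
          list(alias = segs[[1L]], var = paste(segs[-1L], collapse = "."),
               expr = .compile_expr(eq$expr))
      } else if (.expression_has_random(eq$expr)) {
        plan$aux_rand[[tgt]] <- .compile_expr(eq$expr)
      } else {
        plan$aux_det[[tgt]] <- list(expr = .compile_expr(eq$expr),
                                    deps = expression_vars(eq$expr))
      }
    } else {
      if (is_ep) {
        plan$ep_events[[length(plan$ep_events) + 1L]] <-
          list(alias = segs[[1L]], var = paste(segs[-1L], collapse = "."),
               cond = .compile_expr(cond), expr = .compile_expr(eq$expr))
      } else {
        plan$events[[length(plan$events) + 1L]] <-
          list(target = tgt, cond = .compile_expr(cond), expr = .compile_expr(eq$expr))
      }
    }
  }

  # topological order of deterministic algebraic equations
  plan$aux_det <- .topo_aux(plan$aux_det, entry$prefix)

  # precomputed gather descriptors (avoid string work per step)
  split1 <- function(nm) {
    segs <- identifier_segments(nm)
    list(name = nm, alias = segs[[1L]], var = paste(segs[-1L], collapse = "."))
  }
  plan$gather_desc <- lapply(plan$gather, split1)
  plan$prev_desc <- lapply(plan$prev_gather, function(nm) {
    d <- split1(nm)
    d$bind <- paste0(".prev.", nm)
    d$var <- paste0(".prev.", d$var)
    d
  })

  # a state variable may not also have an unconditioned algebraic equation
  aux_targets <- c(names(plan$aux_det), names(plan$aux_rand))
  both <- intersect(names(plan$deriv), aux_targets)
  if (length(both))
    stop(sprintf("group '%s': '%s' has both a differential and an algebraic equation",
                 entry$prefix, both[[1L]]), call. = FALSE)
  # ... nor may an event target: the per-stage algebraic refresh would
  # overwrite the event's assignment (use '@ $init' for the start value)
  both2 <- intersect(vapply(plan$events, function(e) e$target, character(1)), aux_targets)
  if (length(both2))
    stop(sprintf("group '%s': '%s' is both an algebraic target and an event target; initialize it with '@ $init' instead",
                 entry$prefix, both2[[1L]]), call. = FALSE)

  integ <- character(0)
  for (tgt in names(plan$deriv)) {
    integ <- c(integ, tgt)
    if (plan$deriv[[tgt]]$order == 2L) integ <- c(integ, paste0(tgt, "'"))
  }
  plan$integ <- integ
  plan$vars <- unique(c(
    integ, names(plan$aux_det), names(plan$aux_rand),
    vapply(plan$init, function(e) if (e$order == 0L) e$target else paste0(e$target, "'"), ""),
    vapply(plan$events, function(e) e$target, character(1))))
  plan
}

.topo_aux <- function(aux, prefix) {
  if (length(aux) == 0L) return(aux)
  targets <- names(aux)
  ordered <- character(0)
  state <- stats::setNames(rep(0L, length(targets)), targets)
  visit <- function(t) {
    if (state[[t]] == 2L) return()
    if (state[[t]] == 1L)
      stop(sprintf("group '%s': algebraic equations form a cycle at '%s'", prefix, t),
           call. = FALSE)
    state[[t]] <<- 1L
    for (d in intersect(aux[[t]]$deps, targets)) visit(d)
    state[[t]] <<- 2L
    ordered <<- c(ordered, t)
  }
  for (t in targets) visit(t)
  aux[ordered]
}

# Compile all groups of a model and cross-link accumulator inputs and
# previous-value requirements.
.compile_model_plans <- function(cm) {
  pops <- lapply(cm$populations, .compile_template, kind = "pop")
  conns <- lapply(cm$connections, .compile_template, kind = "conn")

  for (cp in conns) {
    for (acc in cp$ep_accum) {
      pop <- cp$endpoints[[acc$alias]]
      if (acc$var %in% c(names(pops[[pop]]$aux_det), names(pops[[pop]]$aux_rand)))
        stop(sprintf("variable '%s' of population '%s' is both an algebraic target and a connection accumulator",
                     acc$var, pop), call. = FALSE)
      pops[[pop]]$input_vars <- union(pops[[pop]]$input_vars, acc$var)
      pops[[pop]]$vars <- union(pops[[pop]]$vars, acc$var)
    }
    for (ed in cp$ep_deriv) {
      pop <- cp$endpoints[[ed$alias]]
      if (!ed$var %in% pops[[pop]]$integ)
        stop(sprintf("connection '%s' contributes to %s.%s' but '%s' is not a state variable of population '%s'",
                     cp$prefix, ed$alias, ed$var, ed$var, pop), call. = FALSE)
    }
    for (pg in cp$prev_gather) {
      segs <- identifier_segments(pg)
      pop <- cp$endpoints[[segs[[1L]]]]
      pops[[pop]]$prev_local <- union(pops[[pop]]$prev_local,
                                      paste(segs[-1L], collapse = "."))
    }
    for (ev in cp$ep_events) {
      pop <- cp$endpoints[[ev$alias]]
      pops[[pop]]$vars <- union(pops[[pop]]$vars, ev$var)
    }
  }
  list(pops = pops, conns = conns)
}
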