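# Reference simulator: instantiate populations and connections from a
# compiled model, advance them with fixed-step synchronous integration
# (Euler or classical RK4), apply event-triggered assignments, and run
# structural updates (type transitions: split, differentiate, die)
# between steps.
#
# State layout: one mutable environment per group (population or
# connection template) holding per-instance value vectors; expressions
# compiled by the plan layer are evaluated directly in those
# environments, so all arithmetic is vectorized over instances.

#' Simulation configuration
#'
#' @param dt Integration step, in the model's time unit (the packaged
#'   neural fixtures use milliseconds; default 0.01).
#' @param duration Total simulated time (same unit).
#' @param integrator `"rk4"` (classical Runge-Kutta) or `"euler"`.
#' @param seed Integer seed; every random draw of the run (wiring,
#'   structural decisions, noise functions) derives from it through
#'   three fixed sub-streams, so equal seeds give identical runs.
#' @param record List of recording requests, each
#'   `list(population = <prefix>, variable = <name>)`; the variable is
#'   sampled for every live instance at every step.
#' @param spike_threshold Upward-crossing threshold for spike-raster
#'   extraction (default 0).
#' @param spike_variable Variable watched for threshold crossings
#'   (default `"V"`).
#' @param spike_populations Population prefixes to watch; `NULL` means
#'   every population that defines the spike variable.
#' @param wiring_seed Optional separate seed for the connection-wiring
#'   stream; `NULL` (default) derives it from `seed`.  Ensembles use
#'   this to hold network structure fixed while dynamics seeds vary.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(dt = 0.01, duration = 1, integrator = c("rk4", "euler"),
                              seed = 1L, record = list(), spike_threshold = 0,
                              spike_variable = "V", spike_populations = NULL,
                              wiring_seed = NULL) {
  integrator <- match.arg(integrator)
  stopifnot(dt > 0, duration >= 0)
  structure(list(dt = dt, duration = duration, integrator = integrator,
                 seed = as.integer(seed), record = record,
                 spike_threshold = spike_threshold, spike_variable = spike_variable,
                 spike_populations = spike_populations,
                 wiring_seed = if (is.null(wiring_seed)) NULL else as.integer(wiring_seed)),
            class = "simulation_config")
}

#' Derive a child seed from a base seed
#'
#' SHA-256 of `"<base>:<index>"`, truncated to 31 bits, so derived
#' seeds are valid R seeds, mutually independent for practical
#' purposes, and fully determined by the recorded base seed and index.
#'
#' @param base_seed Integer base seed.
#' @param index Integer derivation index (run index, stream number...).
#' @return A non-negative integer below 2^31.
#' @export
derive_seed <- function(base_seed, index) {
  h <- .sha256_hex(paste0(base_seed, ":", index))
  digits <- strtoi(strsplit(substr(h, 1L, 8L), "")[[1L]], 16L)
  bits <- 0
  for (d in digits) bits <- (bits * 16 + d) %% 2^31
  as.integer(bits)
}

.stream_do <- function(state, name, f) {
  glob <- globalenv()
  old <- if (exists(".Random.seed", envir = glob, inherits = FALSE))
    get(".Random.seed", envir = glob) else NULL
  assign(".Random.seed", state$streams[[name]], envir = glob)
  on.exit({
    state$streams[[name]] <- get(".Random.seed", envir = glob)
    if (is.null(old)) rm(".Random.seed", envir = glob)
    else assign(".Random.seed", old, envir = glob)
  })
  f()
}

.seed_state <- function(seed) {
  glob <- globalenv()
  old <- if (exists(".Random.seed", envir = glob, inherits = FALSE))
    get(".Random.seed", envir = glob) else NULL
  set.seed(seed)
  out <- get(".Random.seed", envir = glob)
  if (is.null(old)) rm(".Random.seed", envir = glob)
  else assign(".Random.seed", old, envir = glob)
  out
}

# ---- instantiation -------------------------------------------------------

.make_group_env <- function(state, plan) {
  g <- new.env(parent = emptyenv())
  g$plan <- plan
  g$vals <- new.env(parent = state$globals)
  g$n <- 0L
  g$ids <- numeric(0)
  g$next_id <- 0
  g$dead <- logical(0)
  g$initial <- 0L
  g$created <- 0L
  g$died <- 0L
  if (plan$kind == "conn") g$slots <- stats::setNames(
    rep(list(integer(0)), length(plan$endpoints)), names(plan$endpoints))
  vals <- g$vals
  vals$.len <- 0L
  vals$.rand_u <- function() .stream_do(state, state$active, function() stats::runif(vals$.len))
  vals$.rand_g <- function() .stream_do(state, state$active, function() stats::rnorm(vals$.len))
  for (v in plan$vars) vals[[v]] <- numeric(0)
  vals[["$index"]] <- numeric(0)
  vals[["$n"]] <- 0
  g
}

# Evaluate with result recycled to the group's instance count.
.ev <- function(expr, env, n) {
  out <- eval(expr, env)
  if (length(out) == n) out else rep_len(out, n)
}

# Bind gathered endpoint variables (and requested previous values) for a
# connection group into an environment, using the given slot vectors.
.bind_gather <- function(state, plan, env, slots) {
  groups <- state$groups
  eps <- plan$endpoints
  for (d in plan$gather_desc) {
    x <- groups[[eps[[d$alias]]]]$vals[[d$var]]
    env[[d$name]] <- if (is.null(x)) numeric(length(slots[[d$alias]]))
                     else if (length(x) == 1L) x  # scalar binding such as $n
                     else x[slots[[d$alias]]]
  }
  for (d in plan$prev_desc) {
    x <- groups[[eps[[d$alias]]]]$vals[[d$var]]
    env[[d$bind]] <- if (is.null(x)) numeric(length(slots[[d$alias]]))
                     else if (length(x) == 1L) x
                     else x[slots[[d$alias]]]
  }
  invisible(env)
}

# Append m fresh instances to a group and run its @ $init equations on
# the new block in a scratch environment.  `gather` supplies endpoint
# bindings for connection groups (vectors of length m).  Returns the new
# instance ids.
.spawn_instances <- function(state, g, m, gather = NULL) {
  if (m == 0L) return(numeric(0))
  plan <- g$plan
  new_ids <- g$next_id + seq_len(m) - 1
  g$next_id <- g$next_id + m
  slots <- g$n + seq_len(m)
  for (v in plan$vars) g$vals[[v]] <- c(g$vals[[v]], numeric(m))
  g$ids <- c(g$ids, new_ids)
  g$dead <- c(g$dead, logical(m))
  g$n <- g$n + m
  g$vals$.len <- g$n
  g$vals[["$index"]] <- g$ids
  g$vals[["$n"]] <- g$n

  tenv <- new.env(parent = state$globals)
  tenv$.len <- m
  tenv$.rand_u <- function() .stream_do(state, state$active, function() stats::runif(tenv$.len))
  tenv$.rand_g <- function() .stream_do(state, state$active, function() stats::rnorm(tenv$.len))
  for (v in plan$vars) tenv[[v]] <- numeric(m)
  tenv[["$index"]] <- new_ids
  tenv[["$n"]] <- g$n
  tenv[["$init"]] <- 1
  if (!is.null(gather)) for (nm in names(gather)) tenv[[nm]] <- gather[[nm]]

  old_active <- state$active
  state$active <- "noise"
  run_aux <- function() {
    for (t in names(plan$aux_det)) tenv[[t]] <- .ev(plan$aux_det[[t]]$expr, tenv, m)
  }
  for (t in names(plan$aux_rand)) tenv[[t]] <- .ev(plan$aux_rand[[t]], tenv, m)
  for (ie in plan$init) {
    run_aux()
    tgt <- if (ie$order == 0L) ie$target else paste0(ie$target, "'")
    tenv[[tgt]] <- .ev(ie$expr, tenv, m)
  }
  run_aux()
  state$active <- old_active

  for (v in plan$vars) g$vals[[v]][slots] <- tenv[[v]]
  new_ids
}

# Enumerate candidate pairs, evaluate $p, and create connection
# instances.  a_slots/b_slots index the endpoint populations.
.wire_candidates <- function(state, cname, a_slots, b_slots) {
  g <- state$groups[[cname]]
  plan <- g$plan
  na <- length(a_slots); nb <- length(b_slots)
  if (na == 0L || nb == 0L) return(invisible(0L))
  src <- rep(a_slots, each = nb)
  dst <- rep(b_slots, times = na)
  m <- length(src)
  aliases <- names(plan$endpoints)
  slots <- stats::setNames(list(src, dst), aliases)

  accept <- rep(TRUE, m)
  if (!is.null(plan$p_expr)) {
    tenv <- new.env(parent = state$globals)
    tenv$.len <- m
    tenv$.rand_u <- function() .stream_do(state, state$active, function() stats::runif(tenv$.len))
    tenv$.rand_g <- function() .stream_do(state, state$active, function() stats::rnorm(tenv$.len))
    for (v in plan$vars) tenv[[v]] <- numeric(m)
    .bind_gather(state, plan, tenv, slots)
    old_active <- state$active
    state$active <- "wiring"
    for (t in names(plan$aux_det)) tenv[[t]] <- .ev(plan$aux_det[[t]]$expr, tenv, m)
    p <- .ev(plan$p_expr, tenv, m)
    state$active <- old_active
    if (is.logical(p)) {
      accept <- p & !is.na(p)
    } else {
      if (any(p < 0 | p > 1, na.rm = TRUE)) {
        warning(sprintf("connection '%s': $p outside [0, 1]; clamping", cname))
        p <- pmin(pmax(p, 0), 1)
      }
      u <- .stream_do(state, "wiring", function() stats::runif(m))
      accept <- u < p
    }
  }
  src <- src[accept]; dst <- dst[accept]
  k <- length(src)
  if (k == 0L) return(invisible(0L))
  gather <- local({
    tmp <- new.env(parent = emptyenv())
    .bind_gather(state, plan, tmp, stats::setNames(list(src, dst), aliases))
    as.list(tmp)
  })
  old_active <- state$active
  state$active <- "wiring"
  ids <- .spawn_instances(state, g, k, gather = gather)
  state$active <- old_active
  g$slots[[aliases[[1L]]]] <- c(g$slots[[aliases[[1L]]]], src)
  g$slots[[aliases[[2L]]]] <- c(g$slots[[aliases[[2L]]]], dst)
  g$created <- g$created + k
  invisible(k)
}

#' Wire connection instances for candidate endpoint pairs
#'
#' Evaluates the connection template's `$p` equation over the candidate
#' pairs (endpoint variables, `$index`, and `$n` in scope) and creates a
#' connection instance for each accepted pair: every pair when `$p` is
#' a true predicate, or a Bernoulli draw from the wiring stream when
#' `$p` is a probability.  Called automatically at instantiation for
#' all pairs and after structural changes for new pairs only.
#'
#' @param state A `"simulation_state"`.
#' @param prefix Connection template prefix.
#' @param a_slots,b_slots Integer slot indices into the two endpoint
#'   populations (defaults: all current instances).
#' @return Number of connection instances created, invisibly.
#' @export
connect_pairs <- function(state, prefix, a_slots = NULL, b_slots = NULL) {
  g <- state$groups[[prefix]]
  if (is.null(g) || g$plan$kind != "conn") stop("no connection template '", prefix, "'")
  popA <- state$groups[[g$plan$endpoints[[1L]]]]
  popB <- state$groups[[g$plan$endpoints[[2L]]]]
  .wire_candidates(state, prefix,
                   a_slots %||% seq_len(popA$n),
                   b_slots %||% seq_len(popB$n))
}

#' Instantiate a compiled model
#'
#' Creates `$n` instances per population, evaluates `@ $init`
#' equations, wires connection instances over all candidate pairs, and
#' seeds the run's random streams (wiring, structural, noise -- all
#' derived from `config$seed`).
#'
#' @param model A `"compiled_model"`.
#' @param config A `"simulation_config"`.
#' @return A mutable object of class `"simulation_state"`.
#' @export
instantiate <- function(model, config) {
  stopifnot(inherits(model, "compiled_model"), inherits(config, "simulation_config"))
  plans <- .compile_model_plans(model)
  state <- new.env(parent = emptyenv())
  class(state) <- "simulation_state"
  state$model <- model
  state$config <- config
  state$time <- 0
  state$nstep <- 0L
  state$active <- "noise"
  wseed <- config$wiring_seed %||% config$seed
  state$streams <- list(wiring = .seed_state(derive_seed(wseed, 1L)),
                        structural = .seed_state(derive_seed(config$seed, 2L)),
                        noise = .seed_state(derive_seed(config$seed, 3L)))

  globals <- new.env(parent = baseenv())
  globals[["$t"]] <- 0
  globals[["$dt"]] <- config$dt
  globals[["$init"]] <- 0
  state$globals <- globals
  # model-scope constants, evaluated once (declaration order; repeated
  # passes let later constants see earlier ones)
  genv <- new.env(parent = globals)
  genv$.len <- 1L
  genv$.rand_u <- function() .stream_do(state, "noise", function() stats::runif(1L))
  genv$.rand_g <- function() .stream_do(state, "noise", function() stats::rnorm(1L))
  gl <- Filter(function(eq) eq$order == 0L && is.null(eq$condition), model$globals)
  gl_det <- Filter(function(eq) !.expression_has_random(eq$expr), gl)
  refresh <- function() for (eq in gl_det)
    globals[[eq$target]] <- eval(.compile_expr(eq$expr), genv)
  for (eq in gl) {
    refresh()
    globals[[eq$target]] <- eval(.compile_expr(eq$expr), genv)
  }
  refresh()

  state$groups <- list()
  for (plan in c(plans$pops, plans$conns))
    state$groups[[plan$prefix]] <- .make_group_env(state, plan)

  # spike bookkeeping
  spike_pops <- config$spike_populations
  if (is.null(spike_pops))
    spike_pops <- names(plans$pops)[vapply(plans$pops, function(p)
      config$spike_variable %in% p$vars, logical(1))]
  state$spike_pops <- spike_pops
  for (sp in spike_pops)
    state$groups[[sp]]$plan$prev_local <-
      union(state$groups[[sp]]$plan$prev_local, config$spike_variable)

  state$raster <- list()
  state$events <- list()
  state$series <- list()
  state$counts <- list()

  # populations
  for (pname in names(plans$pops)) {
    g <- state$groups[[pname]]
    n <- 1
    if (!is.null(g$plan$n_expr)) {
      tenv <- new.env(parent = globals)
      tenv$.len <- 1L
      tenv$.rand_u <- function() .stream_do(state, "noise", function() stats::runif(1L))
      tenv$.rand_g <- function() .stream_do(state, "noise", function() stats::rnorm(1L))
      n <- eval(g$plan$n_expr, tenv)
    }
    if (length(n) != 1L || !is.finite(n) || n < 0 || abs(n - round(n)) > 1e-9)
      stop(sprintf("population '%s': $n must be a non-negative integer, got %s",
                   pname, format(n)), call. = FALSE)
    .spawn_instances(state, g, as.integer(round(n)))
    g$initial <- g$n
  }

  # connections: all candidate pairs
  for (cname in names(plans$conns)) {
    g <- state$groups[[cname]]
    popA <- state$groups[[g$plan$endpoints[[1L]]]]
    popB <- state$groups[[g$plan$endpoints[[2L]]]]
    .wire_candidates(state, cname, seq_len(popA$n), seq_len(popB$n))
    g$initial <- g$n
    g$created <- 0L
  }

  .save_prev(state)
  .record_state(state)
  state
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation state: t = %g, %d group(s)>\n", x$time, length(x$groups)))
  for (nm in names(x$groups))
    cat(sprintf("  %s [%s]: %d instance(s)\n", nm, x$groups[[nm]]$plan$kind, x$groups[[nm]]$n))
  invisible(x)
}

.save_prev <- function(state) {
  for (g in state$groups) {
    for (v in g$plan$prev_local)
      g$vals[[paste0(".prev.", v)]] <- g$vals[[v]]
  }
}

# ---- derivative evaluation ----------------------------------------------

.snapshot_y <- function(state) {
  lapply(state$groups, function(g)
    stats::setNames(lapply(g$plan$integ, function(v) g$vals[[v]]), g$plan$integ))
}

.bind_y <- function(state, y) {
  for (nm in names(y)) {
    vals <- state$groups[[nm]]$vals
    yv <- y[[nm]]
    for (v in names(yv)) vals[[v]] <- yv[[v]]
  }
}

.compute_derivs <- function(state) {
  groups <- state$groups
  d <- lapply(groups, function(g)
    stats::setNames(vector("list", length(g$plan$integ)), g$plan$integ))

  for (g in groups) {
    if (g$plan$kind != "pop") next
    for (v in g$plan$input_vars) g$vals[[v]] <- numeric(g$n)
  }
  for (g in groups) {
    if (g$plan$kind != "conn") next
    plan <- g$plan
    .bind_gather(state, plan, g$vals, g$slots)
    for (t in names(plan$aux_det)) g$vals[[t]] <- .ev(plan$aux_det[[t]]$expr, g$vals, g$n)
    for (acc in plan$ep_accum) {
      pop <- state$groups[[plan$endpoints[[acc$alias]]]]
      val <- .ev(acc$expr, g$vals, g$n)
      pop$vals[[acc$var]] <- pop$vals[[acc$var]] +
        .accum_sum(val, g$slots[[acc$alias]], pop$n)
    }
  }
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (g$plan$kind != "pop") next
    plan <- g$plan
    for (t in names(plan$aux_det)) g$vals[[t]] <- .ev(plan$aux_det[[t]]$expr, g$vals, g$n)
    for (tgt in names(plan$deriv)) {
      de <- plan$deriv[[tgt]]
      if (de$order == 1L) {
        d[[nm]][[tgt]] <- .ev(de$expr, g$vals, g$n)
      } else {
        d[[nm]][[tgt]] <- g$vals[[paste0(tgt, "'")]]
        d[[nm]][[paste0(tgt, "'")]] <- .ev(de$expr, g$vals, g$n)
      }
    }
  }
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (g$plan$kind != "conn") next
    plan <- g$plan
    for (tgt in names(plan$deriv)) {
      de <- plan$deriv[[tgt]]
      if (de$order == 1L) {
        d[[nm]][[tgt]] <- .ev(de$expr, g$vals, g$n)
      } else {
        d[[nm]][[tgt]] <- g$vals[[paste0(tgt, "'")]]
        d[[nm]][[paste0(tgt, "'")]] <- .ev(de$expr, g$vals, g$n)
      }
    }
    for (ed in plan$ep_deriv) {
      popname <- plan$endpoints[[ed$alias]]
      pop <- state$groups[[popname]]
      val <- .ev(ed$expr, g$vals, g$n)
      contrib <- .accum_sum(val, g$slots[[ed$alias]], pop$n)
      cur <- d[[popname]][[ed$var]]
      d[[popname]][[ed$var]] <- if (is.null(cur)) contrib else cur + contrib
    }
  }
  for (nm in names(d))
    for (v in names(d[[nm]]))
      if (is.null(d[[nm]][[v]])) d[[nm]][[v]] <- numeric(state$groups[[nm]]$n)
  d
}

.y_axpy <- function(y, k, a) {
  for (nm in names(y))
    for (v in names(y[[nm]]))
      y[[nm]][[v]] <- y[[nm]][[v]] + a * k[[nm]][[v]]
  y
}

.k_combine <- function(k1, k2, k3, k4) {
  for (nm in names(k1))
    for (v in names(k1[[nm]]))
      k1[[nm]][[v]] <- (k1[[nm]][[v]] + 2 * k2[[nm]][[v]] + 2 * k3[[nm]][[v]] + k4[[nm]][[v]]) / 6
  k1
}

.check_finite <- function(state) {
  for (nm in names(state$groups)) {
    g <- state$groups[[nm]]
    for (v in g$plan$integ) {
      x <- g$vals[[v]]
      bad <- which(!is.finite(x))
      if (length(bad))
        stop(sprintf("non-finite value in '%s' of group '%s' (instance id %s) at t = %g",
                     v, nm, format(g$ids[bad[[1L]]]), state$time), call. = FALSE)
    }
  }
}

# ---- stepping ------------------------------------------------------------

#' Advance the simulation by one step
#'
#' Synchronous update: previous-step values are saved (for `crossed()`
#' edge detection), per-step random draws are made, all derivatives are
#' evaluated from the stage state (connection contributions added into
#' their endpoints' accumulators), the integrator advances every state
#' variable, conditioned order-0 equations whose condition holds assign
#' after the advance, and structural `$type` transitions are applied
#' between steps.
#'
#' @param state A `"simulation_state"`; modified in place.
#' @return The state, invisibly.
#' @export
sim_step <- function(state) {
  dt <- state$config$dt
  .save_prev(state)

  # per-step random algebraic values (noise stream)
  state$active <- "noise"
  for (g in state$groups) {
    plan <- g$plan
    if (length(plan$aux_rand) == 0L) next
    if (plan$kind == "conn") .bind_gather(state, plan, g$vals, g$slots)
    for (t in names(plan$aux_rand)) g$vals[[t]] <- .ev(plan$aux_rand[[t]], g$vals, g$n)
  }

  y0 <- .snapshot_y(state)
  if (state$config$integrator == "euler") {
    k1 <- .compute_derivs(state)
    y1 <- .y_axpy(y0, k1, dt)
  } else {
    k1 <- .compute_derivs(state)
    .bind_y(state, .y_axpy(y0, k1, dt / 2))
    k2 <- .compute_derivs(state)
    .bind_y(state, .y_axpy(y0, k2, dt / 2))
    k3 <- .compute_derivs(state)
    .bind_y(state, .y_axpy(y0, k3, dt))
    k4 <- .compute_derivs(state)
    y1 <- .y_axpy(y0, .k_combine(k1, k2, k3, k4), dt)
  }
  .bind_y(state, y1)
  state$time <- state$time + dt
  state$globals[["$t"]] <- state$time
  state$nstep <- state$nstep + 1L
  .check_finite(state)

  # event-triggered assignments (after the advance)
  state$active <- "noise"
  for (nm in names(state$groups)) {
    g <- state$groups[[nm]]
    plan <- g$plan
    if (g$n == 0L) next
    if (plan$kind == "conn" &&
        (length(plan$events) || length(plan$ep_events) || length(plan$gather)))
      .bind_gather(state, plan, g$vals, g$slots)
    for (ev in plan$events) {
      keep <- .ev(ev$cond, g$vals, g$n)
      keep <- keep & !is.na(keep)
      if (!any(keep)) next
      val <- .ev(ev$expr, g$vals, g$n)
      g$vals[[ev$target]][keep] <- val[keep]
    }
    for (ev in plan$ep_events) {
      keep <- .ev(ev$cond, g$vals, g$n)
      keep <- keep & !is.na(keep)
      if (!any(keep)) next
      pop <- state$groups[[plan$endpoints[[ev$alias]]]]
      val <- .ev(ev$expr, g$vals, g$n)
      cur <- pop$vals[[ev$var]][g$slots[[ev$alias]]]
      delta <- val - cur
      pop$vals[[ev$var]] <- pop$vals[[ev$var]] +
        .accum_sum(delta[keep], g$slots[[ev$alias]][keep], pop$n)
    }
  }

  .detect_spikes(state)
  structural_update(state)
  .record_state(state)
  invisible(state)
}

.detect_spikes <- function(state) {
  th <- state$config$spike_threshold
  v <- state$config$spike_variable
  for (sp in state$spike_pops) {
    g <- state$groups[[sp]]
    if (g$n == 0L) next
    prev <- g$vals[[paste0(".prev.", v)]]
    now <- g$vals[[v]]
    if (length(prev) != length(now)) next  # population changed shape this step
    fired <- prev < th & now >= th
    if (any(fired))
      state$raster[[length(state$raster) + 1L]] <-
        list(population = sp, id = g$ids[fired], time = state$time)
  }
}

.log_event <- function(state, population, kind, id, detail = "") {
  state$events[[length(state$events) + 1L]] <-
    list(time = state$time, population = population, event = kind,
         id = id, detail = detail)
}

# ---- structural dynamics -------------------------------------------------

#' Apply structural `$type` transitions
#'
#' For each instance whose `$type` condition fired this step (first
#' matching equation wins, in template order): an empty list `[]` kills
#' the instance; `[Q]` turns it into a part-Q instance; `[Q, R, ...]`
#' replaces it with one new instance per listed part.  Values with
#' matching names are copied into each new instance (after the target
#' part's own `@ $init` equations run); all new instances get fresh
#' ids, and new candidate pairs become eligible for connection wiring
#' immediately.  Decisions draw from the run's structural random
#' stream.
#'
#' @param state A `"simulation_state"`; modified in place.
#' @return The state, invisibly.
#' @export
structural_update <- function(state) {
  pops <- Filter(function(g) g$plan$kind == "pop", state$groups)
  if (!any(vapply(pops, function(g) length(g$plan$type_eqs) > 0L, logical(1))))
    return(invisible(state))

  state$active <- "structural"
  actions <- list()
  for (nm in names(pops)) {
    g <- pops[[nm]]
    plan <- g$plan
    if (length(plan$type_eqs) == 0L || g$n == 0L) next
    for (t in names(plan$aux_det)) g$vals[[t]] <- .ev(plan$aux_det[[t]]$expr, g$vals, g$n)
    decided <- rep(NA_integer_, g$n)
    for (k in seq_along(plan$type_eqs)) {
      cond <- plan$type_eqs[[k]]$cond
      hit <- if (isTRUE(cond)) rep(TRUE, g$n) else {
        h <- .ev(cond, g$vals, g$n); h & !is.na(h)
      }
      sel <- hit & is.na(decided)
      decided[sel] <- k
    }
    for (k in seq_along(plan$type_eqs)) {
      slots <- which(decided == k)
      if (length(slots))
        actions[[length(actions) + 1L]] <- list(pop = nm, k = k, slots = slots)
    }
  }
  if (length(actions) == 0L) {
    state$active <- "noise"
    return(invisible(state))
  }

  created_ids <- lapply(state$groups, function(g) numeric(0))
  part_of <- vapply(pops, function(g) g$plan$part, "")

  for (act in actions) {
    src <- state$groups[[act$pop]]
    targets <- src$plan$type_eqs[[act$k]]$parts
    parent_ids <- src$ids[act$slots]
    kind <- if (length(targets) == 0L) "death"
            else if (length(targets) == 1L) "transition" else "split"
    child_desc <- character(length(act$slots))
    for (q in targets) {
      dest_name <- names(part_of)[part_of == q]
      if (length(dest_name) == 0L)
        stop(sprintf("$type transition in '%s' targets part '%s', which is not a population of the model",
                     act$pop, q), call. = FALSE)
      if (length(dest_name) > 1L)
        stop(sprintf("$type transition in '%s' targets part '%s', which is ambiguous among populations %s",
                     act$pop, q, paste(dest_name, collapse = ", ")), call. = FALSE)
      dest <- state$groups[[dest_name]]
      new_ids <- .spawn_instances(state, dest, length(act$slots))
      common <- setdiff(intersect(src$plan$vars, dest$plan$vars), "$index")
      new_slots <- match(new_ids, dest$ids)
      for (v in common) dest$vals[[v]][new_slots] <- src$vals[[v]][act$slots]
      dest$created <- dest$created + length(new_ids)
      created_ids[[dest_name]] <- c(created_ids[[dest_name]], new_ids)
      child_desc <- paste0(child_desc, ifelse(nzchar(child_desc), ";", ""),
                           dest_name, ":", format(new_ids, trim = TRUE, scientific = FALSE))
    }
    src$dead[act$slots] <- TRUE
    src$died <- src$died + length(act$slots)
    for (i in seq_along(parent_ids))
      .log_event(state, act$pop, kind, parent_ids[[i]],
                 if (length(targets)) child_desc[[i]] else "")
  }

  # snapshot connection endpoint ids before compaction invalidates slots
  for (g in state$groups) {
    if (g$plan$kind != "conn" || g$n == 0L) next
    g$ep_ids <- lapply(stats::setNames(nm = names(g$plan$endpoints)), function(al)
      state$groups[[g$plan$endpoints[[al]]]]$ids[g$slots[[al]]])
  }

  # compact populations: drop dead slots (ids are never reused)
  remapped <- character(0)
  for (nm in names(pops)) {
    g <- state$groups[[nm]]
    if (!any(g$dead)) next
    keep <- !g$dead
    for (v in ls(g$vals, all.names = TRUE)) {
      x <- g$vals[[v]]
      if (is.vector(x) && !is.function(x) && length(x) == g$n && v != ".len")
        g$vals[[v]] <- x[keep]
    }
    g$ids <- g$ids[keep]
    g$dead <- g$dead[keep]
    g$n <- sum(keep)
    g$vals$.len <- g$n
    g$vals[["$n"]] <- g$n
    g$vals[["$index"]] <- g$ids
    remapped <- c(remapped, nm)
  }

  # connections: drop instances with a dead endpoint, remap slots, then
  # wire new candidate pairs (new x all, surviving-old x new)
  for (cname in names(state$groups)) {
    g <- state$groups[[cname]]
    if (g$plan$kind != "conn") next
    aliases <- names(g$plan$endpoints)
    eps <- lapply(aliases, function(al) state$groups[[g$plan$endpoints[[al]]]])
    names(eps) <- aliases
    # remap stored slots through endpoint ids
    if (g$n > 0L) {
      keep <- rep(TRUE, g$n)
      new_slots <- g$slots
      for (al in aliases) {
        epg <- eps[[al]]
        m <- match(g$ep_ids[[al]], epg$ids)
        keep <- keep & !is.na(m)
        new_slots[[al]] <- m
      }
      if (!all(keep)) {
        dropped <- g$ids[!keep]
        for (id in dropped) .log_event(state, cname, "destroy", id)
        g$died <- g$died + sum(!keep)
        for (v in ls(g$vals, all.names = TRUE)) {
          x <- g$vals[[v]]
          if (is.vector(x) && !is.function(x) && length(x) == g$n && v != ".len")
            g$vals[[v]] <- x[keep]
        }
        g$ids <- g$ids[keep]
        g$dead <- g$dead[keep]
        g$n <- sum(keep)
        g$vals$.len <- g$n
        g$vals[["$n"]] <- g$n
        g$vals[["$index"]] <- g$ids
      }
      for (al in aliases) g$slots[[al]] <- new_slots[[al]][keep]
      g$ep_ids <- NULL
    }
    newA <- match(created_ids[[g$plan$endpoints[[1L]]]], eps[[1L]]$ids)
    newB <- match(created_ids[[g$plan$endpoints[[2L]]]], eps[[2L]]$ids)
    newA <- newA[!is.na(newA)]; newB <- newB[!is.na(newB)]
    oldA <- setdiff(seq_len(eps[[1L]]$n), newA)
    if (length(newA)) .wire_candidates(state, cname, newA, seq_len(eps[[2L]]$n))
    if (length(newB)) .wire_candidates(state, cname, oldA, newB)
  }
  state$active <- "noise"
  invisible(state)
}

# ---- recording and results ----------------------------------------------

.record_state <- function(state) {
  pops <- Filter(function(g) g$plan$kind == "pop", state$groups)
  state$counts[[length(state$counts) + 1L]] <-
    c(time = state$time, vapply(pops, function(g) as.numeric(g$n), 0))
  for (req in state$config$record) {
    g <- state$groups[[req$population]]
    if (is.null(g)) stop("record request for unknown group '", req$population, "'")
    key <- paste0(req$population, ".", req$variable)
    state$series[[length(state$series) + 1L]] <-
      list(key = key, time = state$time, ids = g$ids,
           values = rep_len(g$vals[[req$variable]], g$n))
  }
}

#' Run a compiled model
#'
#' Instantiates the model and advances `duration / dt` steps, applying
#' structural updates between steps and recording the configured
#' series, the spike raster (upward crossings of the spike threshold),
#' per-step population counts, and the structural event log.
#'
#' @param model A `"compiled_model"`.
#' @param config A `"simulation_config"`.
#' @return An object of class `"run_result"`: a list with `time`,
#'   `series` (wide data frame, one column per recorded
#'   population.variable.id), `raster` (`neuron_id`, `spike_time`,
#'   `population`), `counts` (per-step population sizes),
#'   `final_counts`, `events`, `bookkeeping` (initial/created/died per
#'   group), and the final `state`.
#' @export
run_simulation <- function(model, config) {
  state <- instantiate(model, config)
  nsteps <- round(config$duration / config$dt)
  for (i in seq_len(nsteps)) sim_step(state)
  .finalize_run(state)
}

.finalize_run <- function(state) {
  counts <- do.call(rbind, state$counts)
  counts <- as.data.frame(counts)

  raster <- if (length(state$raster)) {
    data.frame(
      neuron_id = unlist(lapply(state$raster, function(r) r$id)),
      spike_time = unlist(lapply(state$raster, function(r) rep(r$time, length(r$id)))),
      population = unlist(lapply(state$raster, function(r) rep(r$population, length(r$id)))),
      stringsAsFactors = FALSE)
  } else {
    data.frame(neuron_id = numeric(0), spike_time = numeric(0),
               population = character(0), stringsAsFactors = FALSE)
  }

  events <- if (length(state$events)) {
    data.frame(
      time = vapply(state$events, function(e) e$time, 0),
      population = vapply(state$events, function(e) e$population, ""),
      event = vapply(state$events, function(e) e$event, ""),
      id = vapply(state$events, function(e) as.numeric(e$id), 0),
      detail = vapply(state$events, function(e) e$detail %||% "", ""),
      stringsAsFactors = FALSE)
  } else {
    data.frame(time = numeric(0), population = character(0), event = character(0),
               id = numeric(0), detail = character(0), stringsAsFactors = FALSE)
  }

  series <- .series_wide(state)

  pops <- Filter(function(g) g$plan$kind == "pop", state$groups)
  final_counts <- vapply(pops, function(g) g$n, 0L)
  bookkeeping <- data.frame(
    group = names(state$groups),
    kind = vapply(state$groups, function(g) g$plan$kind, ""),
    initial = vapply(state$groups, function(g) as.integer(g$initial), 0L),
    created = vapply(state$groups, function(g) as.integer(g$created), 0L),
    died = vapply(state$groups, function(g) as.integer(g$died), 0L),
    alive = vapply(state$groups, function(g) g$n, 0L),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(time = counts$time, series = series, raster = raster,
                 counts = counts, final_counts = final_counts, events = events,
                 bookkeeping = bookkeeping, state = state),
            class = "run_result")
}

.series_wide <- function(state) {
  if (length(state$series) == 0L) {
    times <- vapply(state$counts, function(r) r[["time"]], 0)
    return(data.frame(time = times))
  }
  keys <- unique(vapply(state$series, function(s) s$key, ""))
  times <- unique(vapply(state$series, function(s) s$time, 0))
  out <- data.frame(time = times)
  for (key in keys) {
    recs <- Filter(function(s) s$key == key, state$series)
    ids0 <- recs[[1L]]$ids
    static <- all(vapply(recs, function(r) identical(r$ids, ids0), logical(1)))
    if (static) {
      mat <- do.call(rbind, lapply(recs, function(r) r$values))
      for (j in seq_along(ids0))
        out[[paste0(key, ".", format(ids0[[j]], trim = TRUE, scientific = FALSE))]] <- mat[, j]
      next
    }
    all_ids <- sort(unique(unlist(lapply(recs, function(r) r$ids))))
    for (id in all_ids) {
      col <- rep(NA_real_, length(times))
      for (r in recs) {
        j <- match(r$time, times)
        pos <- match(id, r$ids)
        if (!is.na(pos)) col[[j]] <- r$values[[pos]]
      }
      out[[paste0(key, ".", format(id, trim = TRUE, scientific = FALSE))]] <- col
    }
  }
  out
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run result: %d step(s), t in [0, %g]>\n",
              length(x$time) - 1L, max(x$time)))
  cat("  spikes:", nrow(x$raster), "\n")
  cat("  final counts:", paste(names(x$final_counts), x$final_counts, collapse = ", "), "\n")
  invisible(x)
}

# ---- result writers ------------------------------------------------------

#' Write run-result tables to CSV
#'
#' Stable column layouts: the time series as
#' `time,<population.variable.id>,...`; the spike raster as
#' `neuron_id,spike_time,population`; the event log as
#' `time,population,event,id,detail`.
#'
#' @param result A `"run_result"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(result, path) {
  utils::write.csv(result$series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
write_raster_csv <- function(result, path) {
  utils::write.csv(result$raster, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
write_events_csv <- function(result, path) {
  utils::write.csv(result$events, path, row.names = FALSE)
  invisible(path)
}
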