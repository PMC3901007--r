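# Fixed-step integration, connection coupling, events, structural
# dynamics, determinism, and bookkeeping.

test_that("one Euler step matches the closed form for exponential decay", {
  cm <- compile1(decay_src)
  st <- instantiate(cm, simulation_config(dt = 0.5, duration = 1, integrator = "euler"))
  sim_step(st)
  expect_equal(st$groups$d$vals$V, 1 * (1 - 0.5 / 10))
})

test_that("RK4 reproduces exp(-1) within 1e-6 and converges at fourth order", {
  src <- "model M\npart P\n  x = 1 @ $init\n  x' = -x\npart M\n  include p = P\n"
  cm <- compile1(src)
  res <- run_simulation(cm, simulation_config(dt = 0.1, duration = 1, integrator = "rk4",
                                              record = list(list(population = "p", variable = "x"))))
  xT <- res$series$p.x.0[length(res$time)]
  expect_lt(abs(xT - exp(-1)), 1e-6)

  err <- vapply(c(0.2, 0.1, 0.05), function(h) {
    r <- run_simulation(cm, simulation_config(dt = h, duration = 1, integrator = "rk4",
                                              record = list(list(population = "p", variable = "x"))))
    abs(r$series$p.x.0[length(r$time)] - exp(-1))
  }, 0)
  # halving dt should shrink the error by ~2^4; allow slack for roundoff
  expect_gt(err[[1]] / err[[2]], 8)
  expect_gt(err[[2]] / err[[3]], 8)

  err_e <- vapply(c(0.2, 0.1, 0.05), function(h) {
    r <- run_simulation(cm, simulation_config(dt = h, duration = 1, integrator = "euler",
                                              record = list(list(population = "p", variable = "x"))))
    abs(r$series$p.x.0[length(r$time)] - exp(-1))
  }, 0)
  expect_gt(err_e[[1]] / err_e[[2]], 1.7)
  expect_lt(err_e[[1]] / err_e[[2]], 2.3)
})

test_that("second-order equations integrate via a companion state", {
  # harmonic oscillator x'' = -x, x(0) = 1, x'(0) = 0 -> cos(t)
  src <- "model M\npart P\n  x = 1 @ $init\n  x'' = -x\npart M\n  include p = P\n"
  cm <- compile1(src)
  res <- run_simulation(cm, simulation_config(dt = 0.01, duration = 3.14159,
                                              integrator = "rk4",
                                              record = list(list(population = "p", variable = "x"))))
  expect_lt(abs(res$series$p.x.0[length(res$time)] - cos(3.14159)), 1e-5)
})

test_that("antisymmetric diffusive coupling conserves the population sum", {
  cm <- compile1(cable_toy_src)
  st <- instantiate(cm, simulation_config(dt = 0.05, duration = 0, integrator = "rk4"))
  expect_identical(st$groups$link$n, 2L)  # nearest-neighbor pairs for n = 3
  s0 <- sum(st$groups$c$vals$V)
  for (i in 1:400) sim_step(st)
  expect_equal(sum(st$groups$c$vals$V), s0, tolerance = 1e-12)
  # and the compartments relax toward the common mean
  expect_lt(max(abs(st$groups$c$vals$V - s0 / 3)), 1e-3)
})

test_that("complete bipartite and empty wiring follow $p", {
  src <- function(p) sprintf("model M
part A
  x = 1
part B
  y = 2
part L
  connect a = A, b = B
  $p = %s
part M
  include pa = A
  include pb = B
  include l = L
  pa.$n = 3
  pb.$n = 4
", p)
  st1 <- instantiate(compile1(src("1")), simulation_config(duration = 0))
  expect_identical(st1$groups$l$n, 12L)
  st0 <- instantiate(compile1(src("0")), simulation_config(duration = 0))
  expect_identical(st0$groups$l$n, 0L)
})

test_that("instantiation honors $n, assigns ids from zero, and repeats under a seed", {
  cm <- compile1("model M\npart P\n  x = uniform()\n  $n = 100\npart M\n  include p = P\n")
  st <- instantiate(cm, simulation_config(seed = 5, duration = 0))
  expect_identical(st$groups$p$n, 100L)
  expect_identical(st$groups$p$ids, as.numeric(0:99))
  st2 <- instantiate(cm, simulation_config(seed = 5, duration = 0))
  expect_identical(st$groups$p$vals$x, st2$groups$p$vals$x)
  st3 <- instantiate(cm, simulation_config(seed = 6, duration = 0))
  expect_false(identical(st$groups$p$vals$x, st3$groups$p$vals$x))

  # $n = 0 is a valid degenerate population
  cm0 <- compile1("model M\npart P\n  x' = -x\n  $n = 0\npart M\n  include p = P\n")
  res <- run_simulation(cm0, simulation_config(dt = 0.1, duration = 1))
  expect_identical(res$final_counts[["p"]], 0L)
})

test_that("identical model, config, and seed give identical results", {
  cm <- compile1(division_src(0.2, 20))
  cfg <- simulation_config(dt = 1, duration = 10, integrator = "euler", seed = 123)
  r1 <- run_simulation(cm, cfg)
  r2 <- run_simulation(cm, cfg)
  expect_identical(r1$final_counts, r2$final_counts)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$counts, r2$counts)
})

test_that("duration zero returns initial values only", {
  cm <- compile1(decay_src)
  res <- run_simulation(cm, simulation_config(dt = 0.1, duration = 0,
                                              record = list(list(population = "d", variable = "V"))))
  expect_length(res$time, 1L)
  expect_equal(res$series$d.V.0, 1)
})

test_that("non-finite state aborts with a diagnostic naming variable and instance", {
  src <- "model M\npart P\n  x = 1 @ $init\n  x' = x * x * 1e6\npart M\n  include p = P\n"
  cm <- compile1(src)
  expect_error(run_simulation(cm, simulation_config(dt = 1, duration = 10, integrator = "euler")),
               "non-finite value in 'x'.*instance id")
})

test_that("event assignments trigger on upward crossings only", {
  # x ramps up; the event fires once when x crosses 5, not on later steps
  src <- "model M
part P
  x' = 1
  hits = 0 @ $init
  hits = hits + 1 @ crossed(x, 5)
part M
  include p = P
"
  cm <- compile1(src)
  st <- instantiate(cm, simulation_config(dt = 1, duration = 0, integrator = "euler"))
  for (i in 1:10) sim_step(st)
  expect_equal(st$groups$p$vals$hits, 1)
})

test_that("split, differentiate, and death update counts and bookkeeping", {
  src <- "model M
part A
  $type = [B] @ $t >= 1
part B
  z = 0
part M
  include a = A
  include b = B
  a.$n = 4
  b.$n = 0
"
  cm <- compile1(src)
  res <- run_simulation(cm, simulation_config(dt = 1, duration = 2, integrator = "euler"))
  expect_identical(res$final_counts[["a"]], 0L)
  expect_identical(res$final_counts[["b"]], 4L)
  bk <- res$bookkeeping
  expect_true(all(bk$initial + bk$created - bk$died == bk$alive))
  expect_setequal(res$events$event[res$events$population == "a"], "transition")
})

test_that("a symmetric self-split doubles the population and copies values", {
  src <- "model M
part Cell
  marker = $index + 100 @ $init
  $type = [Cell, Cell] @ $t >= 1 && $t < 1.5
part M
  include cell = Cell
  cell.$n = 1
"
  cm <- compile1(src)
  res <- run_simulation(cm, simulation_config(dt = 1, duration = 2, integrator = "euler"))
  st <- res$state
  expect_identical(res$final_counts[["cell"]], 2L)
  # both children carry the parent's copied marker, under fresh ids
  expect_equal(st$groups$cell$vals$marker, c(100, 100))
  expect_false(any(st$groups$cell$ids == 0))
})

test_that("population bookkeeping holds under stochastic growth every step", {
  cm <- compile1(division_src(0.3, 10))
  st <- instantiate(cm, simulation_config(dt = 1, duration = 0, integrator = "euler", seed = 9))
  g <- st$groups$cell
  for (i in 1:15) {
    sim_step(st)
    expect_identical(g$initial + g$created - g$died, as.integer(g$n))
  }
})

test_that("connections to dead endpoints are destroyed, new instances get wired", {
  src <- "model M
part A
  u = uniform()
  $type = [A, A] @ u < 0.3
  $type = [] @ u >= 0.3 && u < 0.45
part L
  connect x = A, y = A
  $p = 1
part M
  include a = A
  include l = L
  a.$n = 6
"
  cm <- compile1(src)
  st <- instantiate(cm, simulation_config(dt = 1, duration = 0, integrator = "euler", seed = 4))
  for (i in 1:6) {
    sim_step(st)
    n <- st$groups$a$n
    # $p = 1: the connection set must stay the complete digraph on live ids
    expect_identical(st$groups$l$n, as.integer(n * n))
    for (al in c("x", "y"))
      expect_true(all(st$groups$l$slots[[al]] >= 1 & st$groups$l$slots[[al]] <= n))
  }
})

test_that("connection accumulators sum multiple inputs additively", {
  # two sources each add 1 into the sink's input current each step
  src <- "model M
part Src
  s = 1
part Sink
  x' = I
part L
  connect a = Src, b = Sink
  $p = 1
  b.I = a.s
part M
  include s = Src
  include k = Sink
  include l = L
  s.$n = 2
  k.$n = 1
"
  cm <- compile1(src)
  st <- instantiate(cm, simulation_config(dt = 1, duration = 0, integrator = "euler"))
  sim_step(st)
  expect_equal(st$groups$k$vals$x, 2)  # dx/dt = 1 + 1
})

test_that("voltage-clamped gates converge to alpha/(alpha+beta)", {
  repo <- build_hh_cable_fixture()
  # clamp: a bare channel host holding V fixed
  extra <- "part Clamped
  include Na = NaChannel
  include K = KChannel
  V = -20
  Na.m = 0.05 @ $init
  Na.h = 0.9 @ $init
  K.n = 0.1 @ $init
model Clamp
part Clamp
  include c = Clamped
"
  repo2 <- parse_model_text(paste0(serialize_repository(repo), extra))
  cm <- flatten_model(repo2, "Clamp")
  res <- run_simulation(cm, simulation_config(dt = 0.01, duration = 30, integrator = "rk4"))
  vals <- res$state$groups$c$vals
  am <- vals$Na.m_alpha; bm <- vals$Na.m_beta
  ah <- vals$Na.h_alpha; bh <- vals$Na.h_beta
  an <- vals$K.n_alpha; bn <- vals$K.n_beta
  expect_lt(abs(vals$Na.m - am / (am + bm)), 1e-4)
  expect_lt(abs(vals$Na.h - ah / (ah + bh)), 1e-4)
  expect_lt(abs(vals$K.n - an / (an + bn)), 1e-4)
})

test_that("result writers produce stable column layouts", {
  cm <- compile1(decay_src)
  res <- run_simulation(cm, simulation_config(dt = 0.1, duration = 1,
                                              record = list(list(population = "d", variable = "V"))))
  d <- tempfile("runout")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  write_series_csv(res, file.path(d, "series.csv"))
  write_raster_csv(res, file.path(d, "raster.csv"))
  write_events_csv(res, file.path(d, "events.csv"))
  expect_identical(names(read.csv(file.path(d, "series.csv"), check.names = FALSE)),
                   c("time", "d.V.0"))
  expect_identical(names(read.csv(file.path(d, "raster.csv"))),
                   c("neuron_id", "spike_time", "population"))
  expect_identical(names(read.csv(file.path(d, "events.csv"))),
                   c("time", "population", "event", "id", "detail"))
})
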