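# Ensemble planning (step/Monte-Carlo/Latin-hypercube), execution,
# provenance, and repeatability.

test_that("two 11-level step specs give a 121-run full factorial", {
  cm <- compile1(decay_src)
  cm <- flatten_model(parse_model_text(
    "model M\npart Decay\n  V = 1 @ $init\n  V' = -V / tau\n  tau = 10\n  k = 2\npart M\n  include d = Decay\n"))
  specs <- list(parameter_spec("d.tau", "step", c(5, 15), 11),
                parameter_spec("d.k", "step", c(0, 1), 11))
  plan <- plan_ensemble(cm, specs, base_seed = 42)
  expect_identical(nrow(plan$runs), 121L)
  expect_identical(anyDuplicated(plan$runs[c("d.tau", "d.k")]), 0L)
  expect_identical(anyDuplicated(plan$runs$seed), 0L)
  # seeds derivable from base seed and run index
  expect_identical(plan$runs$seed,
                   vapply(plan$runs$run, function(i) derive_seed(42, i), 0L))
  # inclusive endpoints
  expect_setequal(unique(plan$runs$d.tau), seq(5, 15, length.out = 11))
})

test_that("single-level step spec plans one run at the lower bound", {
  cm <- compile1(decay_src)
  plan <- plan_ensemble(cm, list(parameter_spec("d.tau", "step", c(5, 15), 1)), 1)
  expect_identical(nrow(plan$runs), 1L)
  expect_equal(plan$runs$d.tau, 5)
})

test_that("latin hypercube uses every stratum exactly once per parameter", {
  cm <- flatten_model(parse_model_text(
    "model M\npart P\n  a = 1\n  b = 2\npart M\n  include p = P\n"))
  specs <- list(parameter_spec("p.a", "latin_hypercube", c(0, 10), 5),
                parameter_spec("p.b", "latin_hypercube", c(-1, 1), 5))
  plan <- plan_ensemble(cm, specs, base_seed = 7)
  expect_identical(nrow(plan$runs), 5L)
  for (j in 1:2)
    expect_setequal(plan$strata[, j], 0:4)
  # values fall inside their declared ranges
  expect_true(all(plan$runs$p.a >= 0 & plan$runs$p.a <= 10))
  expect_true(all(plan$runs$p.b >= -1 & plan$runs$p.b <= 1))
})

test_that("monte carlo draws jointly and respects ranges and count", {
  cm <- flatten_model(parse_model_text(
    "model M\npart P\n  a = 1\npart M\n  include p = P\n"))
  plan <- plan_ensemble(cm, list(parameter_spec("p.a", "monte_carlo", c(2, 4), 8)), 3)
  expect_identical(nrow(plan$runs), 8L)
  expect_true(all(plan$runs$p.a >= 2 & plan$runs$p.a <= 4))
  # same base seed reproduces the same draws
  plan2 <- plan_ensemble(cm, list(parameter_spec("p.a", "monte_carlo", c(2, 4), 8)), 3)
  expect_identical(plan$runs, plan2$runs)
})

test_that("empty spec list plans a single baseline run", {
  cm <- compile1(decay_src)
  plan <- plan_ensemble(cm, list(), 5)
  expect_identical(nrow(plan$runs), 1L)
})

test_that("invalid paths and counts are rejected at planning time", {
  cm <- compile1(decay_src)
  expect_error(plan_ensemble(cm, list(parameter_spec("d.V", "step", c(0, 1), 3)), 1),
               "differential")
  expect_error(plan_ensemble(cm, list(parameter_spec("d.zz", "step", c(0, 1), 3)), 1),
               "does not resolve")
  expect_error(parameter_spec("d.tau", "step", c(0, 1), 0), "count")
})

test_that("step assignments are unchanged when spec order is permuted", {
  cm <- flatten_model(parse_model_text(
    "model M\npart P\n  a = 1\n  b = 2\npart M\n  include p = P\n"))
  s1 <- list(parameter_spec("p.a", "step", c(0, 2), 3),
             parameter_spec("p.b", "step", c(5, 6), 2))
  p1 <- plan_ensemble(cm, s1, 11)
  p2 <- plan_ensemble(cm, rev(s1), 11)
  key1 <- sort(paste(p1$runs$p.a, p1$runs$p.b))
  key2 <- sort(paste(p2$runs$p.a, p2$runs$p.b))
  expect_identical(key1, key2)
})

test_that("executing an ensemble writes per-run results and a complete manifest, repeatably", {
  cm <- compile1(division_src(0.2, 10))
  specs <- list(parameter_spec("cell.p", "step", c(0.1, 0.3), 3))
  # expose the division probability as a constant named p
  cm <- flatten_model(parse_model_text(
    "model M\npart Cell\n  u = uniform()\n  p = 0.2\n  $type = [Cell, Cell] @ u < p\npart M\n  include cell = Cell\n  cell.$n = 10\n"))
  plan <- plan_ensemble(cm, specs, base_seed = 21)
  cfg <- simulation_config(dt = 1, duration = 5, integrator = "euler")
  d1 <- tempfile("ens"); d2 <- tempfile("ens")
  m1 <- execute_ensemble(plan, cm, cfg, d1)
  m2 <- execute_ensemble(plan, cm, cfg, d2)
  on.exit(unlink(c(d1, d2), recursive = TRUE))

  expect_length(m1$runs, 3L)
  expect_true(all(vapply(m1$runs, function(r) r$status, "") == "ok"))
  # byte-identical re-execution of every result file
  for (r in m1$runs) {
    for (f in c("series", "raster", "events")) {
      f1 <- readLines(file.path(d1, r$paths[[f]]))
      f2 <- readLines(file.path(d2, r$paths[[f]]))
      expect_identical(f1, f2)
    }
  }
  # manifest records everything needed to re-run: hash, seeds, assignments
  mj <- read_manifest(d1)
  expect_identical(mj$model_hash, cm$content_hash)
  expect_identical(length(mj$runs), 3L)
  for (r in mj$runs) {
    expect_true(!is.null(r$seed))
    expect_true(!is.null(r$assignment$cell.p))
  }
  # distinct assignments reach the simulator: growth differs across runs
  finals <- vapply(mj$runs, function(r) as.numeric(r$final_counts$cell), 0)
  expect_true(finals[[1]] <= finals[[3]])
})

test_that("a failing run is recorded and the ensemble continues", {
  cm <- flatten_model(parse_model_text(
    "model M\npart P\n  x = 1 @ $init\n  x' = x * x * k\n  k = 0\npart M\n  include p = P\n"))
  plan <- plan_ensemble(cm, list(parameter_spec("p.k", "step", c(0, 1e8), 2)), 2)
  d <- tempfile("ens")
  on.exit(unlink(d, recursive = TRUE))
  m <- execute_ensemble(plan, cm, simulation_config(dt = 1, duration = 12, integrator = "euler"), d)
  status <- vapply(m$runs, function(r) r$status, "")
  expect_identical(status, c("ok", "error"))
  expect_match(m$runs[[2]]$error, "non-finite")
})
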