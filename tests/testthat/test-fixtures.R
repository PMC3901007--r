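# Packaged example models: structure, wiring rules, spiking behavior,
# and branching-process expectations against independent oracles.

test_that("all fixture builders produce repositories with no diagnostics", {
  expect_length(validate_repository(build_hh_cable_fixture()), 0L)
  expect_length(validate_repository(build_ei_network_fixture(N = 50)), 0L)
  expect_length(validate_repository(build_growth_cone_fixture()), 0L)
  expect_length(validate_repository(build_neurogenesis_fixture()), 0L)
})

test_that("packaged fixture files match their builders", {
  cases <- list(
    hh_cable.part.txt = build_hh_cable_fixture(),
    ei_network_n100.part.txt = build_ei_network_fixture(N = 100),
    growth_cone.part.txt = build_growth_cone_fixture(),
    neurogenesis.part.txt = build_neurogenesis_fixture())
  for (nm in names(cases)) {
    from_file <- parse_model_file(fixture_path(nm))
    expect_repo_equal(from_file, cases[[nm]])
  }
})

test_that("the HH cable has seven parts and the expected structure", {
  repo <- build_hh_cable_fixture()
  expect_length(repo$parts, 7L)
  fp <- flatten_part(repo, "HHCompartment")
  targets <- vapply(fp$equations, function(e) e$target, "")
  expect_true(any(startsWith(targets, "Na.")))
  expect_true(any(startsWith(targets, "K.")))
  # channel gating hides the abstract template's unit factor
  expect_identical(deparse_expression(get_equation(fp, "Na.open")$expr), "Na.m ^ 3 * Na.h")
  cm <- flatten_model(repo)
  st <- instantiate(cm, simulation_config(duration = 0))
  expect_identical(st$groups$comp$n, 3L)
  expect_identical(st$groups$cable$n, 2L)  # nearest-neighbor pairs only
  expect_identical(st$groups$cable$slots$A, 1:2)
  expect_identical(st$groups$cable$slots$B, 2:3)
})

test_that("E/I synapse templates share one part and differ only by overrides", {
  repo <- build_ei_network_fixture(N = 50)
  cm <- flatten_model(repo)
  expect_identical(cm$connections$Esyn$part, cm$connections$Isyn$part)
  eE <- get_equation(cm$connections$Esyn$template, "Erev")
  eI <- get_equation(cm$connections$Isyn$template, "Erev")
  expect_identical(deparse_expression(eE$expr), "0")
  expect_identical(deparse_expression(eI$expr), "-80")
})

test_that("the index rule designates exactly 80% of neurons as excitatory sources", {
  for (N in c(100L, 5L)) {
    repo <- build_ei_network_fixture(N = N)
    cm <- flatten_model(repo)
    cm <- override_parameter(cm, "pconn", 1)  # make the predicate deterministic
    st <- instantiate(cm, simulation_config(duration = 0, seed = 2))
    e_sources <- unique(st$groups$n$ids[st$groups$Esyn$slots$A])
    i_sources <- unique(st$groups$n$ids[st$groups$Isyn$slots$A])
    expect_length(e_sources, as.integer(0.8 * N))
    expect_length(i_sources, N - as.integer(0.8 * N))
    expect_true(max(e_sources) < 0.8 * N)
    expect_true(min(i_sources) >= 0.8 * N)
  }
  expect_error(build_ei_network_fixture(N = 4), "at least 5")
})

test_that("growth cone with zero probabilities never changes the tree", {
  repo <- build_growth_cone_fixture(list(elongate = 0, branch = 0,
                                         differentiate = 0, death = 0), n0 = 3)
  res <- run_simulation(flatten_model(repo),
                        simulation_config(dt = 1, duration = 20, integrator = "euler"))
  expect_identical(res$final_counts[["cone"]], 3L)
  expect_identical(res$final_counts[["seg"]], 0L)
  expect_identical(nrow(res$events), 0L)
})

test_that("certain elongation builds a chain: t segments and one cone after t steps", {
  repo <- build_growth_cone_fixture(list(elongate = 1, branch = 0,
                                         differentiate = 0, death = 0), n0 = 1)
  res <- run_simulation(flatten_model(repo),
                        simulation_config(dt = 1, duration = 12, integrator = "euler"))
  expect_identical(res$final_counts[["cone"]], 1L)
  expect_identical(res$final_counts[["seg"]], 12L)
})

test_that("cone counts follow the branching-process expectation", {
  rates <- list(elongate = 0.15, branch = 0.1, differentiate = 0.03, death = 0.02)
  repo <- build_growth_cone_fixture(rates, n0 = 4)
  cm <- flatten_model(repo)
  tsteps <- 8
  nrep <- 200
  counts <- vapply(seq_len(nrep), function(s)
    run_simulation(cm, simulation_config(dt = 1, duration = tsteps, integrator = "euler",
                                         seed = s))$final_counts[["cone"]], 0L)
  expected <- 4 * (1 + rates$branch - rates$differentiate - rates$death)^tsteps
  se <- stats::sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("neurogenesis lineage matches the matrix-power oracle", {
  r <- lineage_rates(p_asym = 0.2, p_sym = 0.15, p_diff = 0.1, p_death = 0.05)
  repo <- build_neurogenesis_fixture(r, n_rgc = 10)
  cm <- flatten_model(repo)
  tsteps <- 10

  # independent oracle: expected counts follow v_{t+1} = v_t M
  M <- rbind(rgc = c(1, r$p_asym, 0),
             npc = c(0, 1 + r$p_sym - r$p_diff - r$p_death, r$p_diff),
             gc  = c(0, 0, 1))
  v <- c(10, 0, 0)
  for (i in seq_len(tsteps)) v <- as.numeric(v %*% M)

  nrep <- 300
  finals <- t(vapply(seq_len(nrep), function(s) {
    fc <- run_simulation(cm, simulation_config(dt = 1, duration = tsteps,
                                               integrator = "euler",
                                               seed = s))$final_counts
    c(fc[["rgc"]], fc[["npc"]], fc[["gc"]])
  }, numeric(3)))
  for (j in 1:3) {
    se <- stats::sd(finals[, j]) / sqrt(nrep)
    expect_lt(abs(mean(finals[, j]) - v[[j]]), 3 * se + 1e-9)
  }
})

test_that("degenerate lineage rates behave deterministically", {
  # no asymmetric division: RGC count is constant
  repo <- build_neurogenesis_fixture(lineage_rates(p_asym = 0), n_rgc = 7)
  res <- run_simulation(flatten_model(repo),
                        simulation_config(dt = 1, duration = 10, integrator = "euler"))
  expect_identical(res$final_counts[["rgc"]], 7L)
  # certain differentiation: every NPC becomes a granule cell next step
  repo2 <- build_neurogenesis_fixture(
    lineage_rates(p_asym = 1, p_sym = 0, p_diff = 1, p_death = 0), n_rgc = 1)
  res2 <- run_simulation(flatten_model(repo2),
                         simulation_config(dt = 1, duration = 3, integrator = "euler"))
  # t1: rgc + npc; t2: rgc + npc + gc(from first npc); t3: 3 gc total
  expect_identical(res2$final_counts[["rgc"]], 1L)
  expect_identical(res2$final_counts[["gc"]], 2L)
  expect_identical(res2$final_counts[["npc"]], 1L)
})

test_that("a suprathreshold step current elicits a propagating spike", {
  cm <- flatten_model(build_hh_cable_fixture())
  res <- run_simulation(cm, simulation_config(
    dt = 0.02, duration = 15, integrator = "rk4",
    record = list(list(population = "comp", variable = "V"))))
  V1 <- res$series$comp.V.0
  V3 <- res$series$comp.V.2
  rest <- V1[[which.max(res$time[res$time <= 1])]]
  expect_gte(max(V1) - rest, 100)
  t1 <- res$raster$spike_time[res$raster$neuron_id == 0][[1L]]
  t3 <- res$raster$spike_time[res$raster$neuron_id == 2][[1L]]
  expect_gt(t3, t1)  # propagation delay
  expect_gt(max(V3), 0)
})
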