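# Inheritance/inclusion flattening, model compilation, hashing,
# parameter overrides.

test_that("child definitions hide parent definitions of the same name", {
  repo <- parse_model_text("part P\n  tau = 10\n  V' = -V / tau\npart C : P\n  tau = 5\n")
  fp <- flatten_part(repo, "C")
  expect_equal(get_equation(fp, "tau")$expr$value, 5)
  expect_identical(deparse_expression(get_equation(fp, "V", 1L)$expr), "-V / tau")
  expect_identical(fp$provenance[[.find_key(fp, "tau")]], "C")
  expect_identical(fp$provenance[[.find_key(fp, "V", 1L)]], "P")
})

test_that("diamond inheritance resolves with leftmost-parent precedence", {
  repo <- parse_model_text("part A\n  x = 1\npart B\n  x = 2\npart C : A, B\n  y = 3\n")
  # hand-resolution: C has no x, A is leftmost, so x = 1
  expect_equal(get_equation(flatten_part(repo, "C"), "x")$expr$value, 1)
  repo2 <- parse_model_text("part A\n  x = 1\npart B\n  x = 2\npart C : B, A\n  y = 3\n")
  expect_equal(get_equation(flatten_part(repo2, "C"), "x")$expr$value, 2)
})

test_that("inclusion prefixes equations and prefixed overrides hide them", {
  repo <- parse_model_text("part K\n  g = 120\npart M\n  include Na = K\n")
  expect_equal(get_equation(flatten_part(repo, "M"), "Na.g")$expr$value, 120)

  repo2 <- parse_model_text("part K\n  g = 120\npart M\n  include Na = K\n  Na.g = 36\n")
  fp2 <- flatten_part(repo2, "M")
  expect_equal(get_equation(fp2, "Na.g")$expr$value, 36)
  # hiding is exact: only one Na.g equation remains, owned by M
  keys <- Filter(function(k) fp2$equations[[k]]$target == "Na.g", names(fp2$equations))
  expect_length(keys, 1L)
  expect_identical(fp2$provenance[[keys]], "M")
})

test_that("nested inclusion composes prefixes and deep overrides win", {
  repo <- parse_model_text(
    "part Q\n  x = 1\npart P\n  include b = Q\npart M\n  include a = P\n  a.b.x = 2\n")
  fp <- flatten_part(repo, "M")
  expect_equal(get_equation(fp, "a.b.x")$expr$value, 2)
  # three-level nest against hand resolution
  repo2 <- parse_model_text(
    "part Q\n  x = 1\n  y = 7\npart P\n  include b = Q\n  b.y = 8\npart M\n  include a = P\n")
  fp2 <- flatten_part(repo2, "M")
  expect_equal(get_equation(fp2, "a.b.x")$expr$value, 1)
  expect_equal(get_equation(fp2, "a.b.y")$expr$value, 8)
})

test_that("references to names defined in an included part are rewritten", {
  repo <- parse_model_text(
    "part K\n  tau = 4\n  g' = -g / tau\npart M\n  include syn = K\n  syn.tau = 9\n")
  fp <- flatten_part(repo, "M")
  expect_identical(deparse_expression(get_equation(fp, "syn.g", 1L)$expr), "-syn.g / syn.tau")
  # free references stay unprefixed and bind in the including scope
  repo2 <- parse_model_text("part K\n  I = g * V\n  g = 2\npart M\n  include c = K\n")
  expect_identical(deparse_expression(get_equation(flatten_part(repo2, "M"), "c.I")$expr),
                   "c.g * V")
})

test_that("flattening an already-flat part is a no-op", {
  repo <- parse_model_text(decay_src)
  f1 <- flatten_part(repo, "Decay")
  eqs1 <- vapply(f1$equations, partsim:::.format_equation, "")
  # re-serialize the flattened equations into a part and flatten again
  body <- paste0("part Flat\n", paste0("  ", sort(unname(eqs1)), "\n", collapse = ""))
  f2 <- flatten_part(parse_model_text(body), "Flat")
  expect_setequal(unname(vapply(f2$equations, partsim:::.format_equation, "")),
                  unname(eqs1))
})

test_that("merge result is independent of processing order when names differ", {
  repo1 <- parse_model_text("part A\n  x = 1\npart B\n  y = 2\npart C : A, B\n")
  repo2 <- parse_model_text("part A\n  x = 1\npart B\n  y = 2\npart C : B, A\n")
  f1 <- flatten_part(repo1, "C")
  f2 <- flatten_part(repo2, "C")
  expect_setequal(unname(vapply(f1$equations, partsim:::.format_equation, "")),
                  unname(vapply(f2$equations, partsim:::.format_equation, "")))
})

test_that("flatten_model builds populations, connections, and sizes", {
  cm <- compile1(cable_toy_src)
  expect_length(cm$populations, 1L)
  expect_length(cm$connections, 1L)
  expect_identical(cm$connections$link$endpoints, c(A = "c", B = "c"))

  cm2 <- compile1("model M\npart P\n  x = 1\n  $n = 100\npart M\n  include p = P\n")
  st <- instantiate(cm2, simulation_config(duration = 0))
  expect_identical(st$groups$p$n, 100L)

  cm3 <- compile1("model M\npart M\n  k = 1\n")
  expect_length(cm3$populations, 0L)
})

test_that("content hash is canonical: reordering lines does not change it", {
  a <- compile1("model M\npart P\n  x = 1\n  y = 2\npart M\n  include p = P\n")
  b <- compile1("model M\npart P\n  y = 2\n  x = 1\npart M\n  include p = P\n")
  expect_identical(a$content_hash, b$content_hash)
  c_ <- compile1("model M\npart P\n  x = 1\n  y = 3\npart M\n  include p = P\n")
  expect_false(identical(a$content_hash, c_$content_hash))
  expect_match(a$content_hash, "^[0-9a-f]{64}$")
})

test_that("override_parameter replaces constants, refuses derivatives, changes hash", {
  cm <- compile1(decay_src)
  cm2 <- override_parameter(cm, "d.tau", 5)
  expect_equal(get_equation(cm2$populations$d$template, "tau")$expr$value, 5)
  expect_equal(get_equation(cm$populations$d$template, "tau")$expr$value, 10)
  expect_false(identical(cm$content_hash, cm2$content_hash))
  expect_error(override_parameter(cm, "d.V", 0), "differential")
  expect_error(override_parameter(cm, "d.nope", 1), "does not resolve")
})
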