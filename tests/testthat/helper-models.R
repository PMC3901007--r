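# Small dialect sources shared across tests, built in code.

decay_src <- "model M
part Decay
  V = 1 @ $init
  V' = -V / tau
  tau = 10
part M
  include d = Decay
  d.$n = 1
"

# two leaky compartments with antisymmetric diffusive coupling
cable_toy_src <- "model M
part Comp
  V' = 0
  V = 10 * $index @ $init
part Coupling
  connect A = Comp, B = Comp
  gr = 0.7
  $p = A.$index + 1 == B.$index
  A.V' = gr * (B.V - A.V)
  B.V' = gr * (A.V - B.V)
part M
  include c = Comp
  include link = Coupling
  c.$n = 3
"

# symmetric division with per-step probability p
division_src <- function(p, n0) sprintf("model M
part Cell
  u = uniform()
  $type = [Cell, Cell] @ u < %g
part M
  include cell = Cell
  cell.$n = %d
", p, n0)

parse1 <- function(src) parse_model_text(src)

compile1 <- function(src) flatten_model(parse_model_text(src))

# structural repository equality, ignoring source-location bookkeeping
expect_repo_equal <- function(a, b) {
  expect_identical(serialize_repository(a), serialize_repository(b))
}

.find_key <- function(fp, target, order = 0L) {
  for (key in names(fp$equations)) {
    eq <- fp$equations[[key]]
    if (eq$target == target && eq$order == order && is.null(eq$condition)) return(key)
  }
  stop("no such equation")
}
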