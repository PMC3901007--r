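# Packaged example models, constructed as dialect source and parsed, so
# the shipped fixture files and the builders cannot drift apart.
#
# 1. A three-compartment Hodgkin-Huxley cable (seven parts: abstract
#    channel, Na and K channels inheriting from it, passive
#    compartment, HH compartment including both channels, the cable
#    coupling connection, and the model).
# 2. An 80/20 excitatory-inhibitory spiking network (Traub-Miles-type
#    HH neuron and conductance-based exponential synapses after the
#    Brette et al. 2007 simulator benchmarks; one neuron part, one
#    synapse part included twice with E/I overrides, Poisson input).
# 3. Structural-dynamics models: a growth cone building a dendritic
#    arbor, and a stem-cell lineage (radial glia -> progenitor ->
#    granule cell).

#' Hodgkin-Huxley membrane parameters
#'
#' Classic squid-axon constants in density units: capacitance in
#' uF/cm^2, conductances in mS/cm^2, potentials in mV, time in ms.
#' `gr` is the lateral (cable) coupling conductance between adjacent
#' compartments, `area` the compartment membrane area in um^2 (so a
#' current injection in pA converts to uA/cm^2 as `I * 100 / area`),
#' and `I` the injected current in pA.
#'
#' @param C,g_Na,g_K,g_leak,E_Na,E_K,E_leak,I,g_r,area See description.
#' @return Named list of parameters.
#' @export
hh_parameters <- function(C = 1, g_Na = 120, g_K = 36, g_leak = 0.3,
                          E_Na = 50, E_K = -77, E_leak = -54.387,
                          I = 10, g_r = 0.3, area = 100) {
  stopifnot(g_Na >= 0, g_K >= 0, g_leak >= 0, g_r >= 0, C > 0, area > 0)
  list(C = C, g_Na = g_Na, g_K = g_K, g_leak = g_leak,
       E_Na = E_Na, E_K = E_K, E_leak = E_leak, I = I, g_r = g_r, area = area)
}

#' Build the three-compartment HH cable model
#'
#' Seven parts: `AbstractChannel` (generic ohmic channel with a gating
#' factor), `NaChannel` and `KChannel` inheriting from it with the
#' standard squid-axon rate functions, `PassiveCompartment` (leaky
#' membrane), `HHCompartment` (inherits the passive membrane and
#' includes both channels under the `Na.` and `K.` prefixes),
#' `CableCoupling` (a connection implementing symmetric diffusive
#' voltage coupling between adjacent compartments), and `CableModel`
#' (a population of `n_compartments` compartments with nearest-neighbor
#' coupling and a step current injected into compartment 0 from
#' `t_on` onward).
#'
#' The rate-function denominators carry a `1e-9` offset so the
#' removable singularities (e.g. at V = -40 mV for alpha_m) stay
#' finite; the perturbation is far below integration error.
#'
#' @param params Parameter list from [hh_parameters()].
#' @param n_compartments Number of cable compartments (default 3).
#' @param t_on Current-step onset time in ms (default 1).
#' @return A validated `"part_repository"` with model entry
#'   `CableModel`.
#' @export
build_hh_cable_fixture <- function(params = hh_parameters(), n_compartments = 3, t_on = 1) {
  p <- params
  src <- sprintf("
model CableModel

part AbstractChannel
  gbar = 0
  Erev = 0
  open = 1
  I = gbar * open * (Erev - V)
  $meta role = ionic conductance template

part NaChannel : AbstractChannel
  gbar = %g
  Erev = %g
  open = m^3 * h
  m_alpha = 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10) + 1e-9)
  m_beta = 4 * exp(-(V + 65) / 18)
  h_alpha = 0.07 * exp(-(V + 65) / 20)
  h_beta = 1 / (1 + exp(-(V + 35) / 10))
  m' = m_alpha * (1 - m) - m_beta * m
  h' = h_alpha * (1 - h) - h_beta * h
  m = m_alpha / (m_alpha + m_beta) @ $init
  h = h_alpha / (h_alpha + h_beta) @ $init

part KChannel : AbstractChannel
  gbar = %g
  Erev = %g
  open = n ^ 4
  n_alpha = 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10) + 1e-9)
  n_beta = 0.125 * exp(-(V + 65) / 80)
  n' = n_alpha * (1 - n) - n_beta * n
  n = n_alpha / (n_alpha + n_beta) @ $init

part PassiveCompartment
  C = %g
  gleak = %g
  Eleak = %g
  Iinj = 0
  V' = (gleak * (Eleak - V) + Iinj) / C
  V = -65 @ $init

part HHCompartment : PassiveCompartment
  include Na = NaChannel
  include K = KChannel
  V' = (gleak * (Eleak - V) + Na.I + K.I + Iinj) / C

part CableCoupling
  connect A = HHCompartment, B = HHCompartment
  gr = %g
  $p = A.$index + 1 == B.$index
  A.V' = gr * (B.V - A.V) / A.C
  B.V' = gr * (A.V - B.V) / B.C

part CableModel
  include comp = HHCompartment
  include cable = CableCoupling
  area = %g
  inj = %g
  comp.$n = %d
  comp.Iinj = (inj * 100 / area) * (comp.$index == 0) * ($t >= %g)
  $meta description = multicompartment cable with active HH membrane
",
    p$g_Na, p$E_Na, p$g_K, p$E_K, p$C, p$g_leak, p$E_leak, p$g_r,
    p$area, p$I, as.integer(n_compartments), t_on)
  repo <- parse_model_text(src)
  stopifnot(length(validate_repository(repo)) == 0L)
  repo
}

#' Build the 80/20 excitatory-inhibitory network model
#'
#' A single population of `N` conductance-based spiking neurons
#' (Traub-Miles-type HH kinetics with threshold parameter VT, a
#' desk-scale variant of the model used in the Brette et al. 2007
#' simulator benchmarks; C in pF, conductances in nS, potentials in
#' mV, time in ms).  Relative to the benchmark constants, the leak
#' reversal sits at -65 mV so an undriven neuron is quiescent, and the
#' peak Na/K conductances are reduced (6000/1800 nS) so explicit
#' fixed-step integration at dt = 0.05 ms remains stable across the
#' whole conductance sweep; spikes still overshoot 0 mV.  One synapse part
#' is included twice: `Esyn` (sources restricted by index to the first
#' 80% of the population) and `Isyn` (the remaining 20%), differing
#' only in model-level overrides of weight, reversal potential, and
#' decay time.  A small Poisson `Spiker` population kicks the network
#' during the first `kick_ms` milliseconds through a separate input
#' synapse.  The two swept conductance coefficients are the model-scope
#' constants `we` and `wi` (nS).
#'
#' @param N Neuron count (>= 5).
#' @param pconn Recurrent connection probability (default 0.1; chosen
#'   for desk-scale networks, where the 2% of the large benchmark nets
#'   would leave almost no recurrence).
#' @param we,wi Default excitatory/inhibitory synaptic weights in nS.
#' @param n_spikers,kick_rate,kick_ms,w_input Input drive: number of
#'   Poisson sources, their rate (spikes/ms), kick duration (ms), and
#'   input synapse weight (nS).
#' @return A validated `"part_repository"` with model entry
#'   `EINetwork`.
#' @export
build_ei_network_fixture <- function(N = 100, pconn = 0.1, we = 6, wi = 67,
                                     n_spikers = 5, kick_rate = 0.04,
                                     kick_ms = 50, w_input = 30) {
  if (N < 5) stop("N must be at least 5 so both classes are non-empty", call. = FALSE)
  src <- sprintf("
model EINetwork

part BretteNeuron
  C = 200
  gL = 10
  EL = -65
  ENa = 50
  EK = -90
  gNa = 6000
  gK = 1800
  VT = -63
  EE = 0
  EI = -80
  tauE = 5
  tauI = 10
  vs = V - VT
  m_alpha = 0.32 * (13 - vs) / (exp((13 - vs) / 4) - 1 + 1e-9)
  m_beta = 0.28 * (vs - 40) / (exp((vs - 40) / 5) - 1 + 1e-9)
  h_alpha = 0.128 * exp((17 - vs) / 18)
  h_beta = 4 / (1 + exp((40 - vs) / 5))
  n_alpha = 0.032 * (15 - vs) / (exp((15 - vs) / 5) - 1 + 1e-9)
  n_beta = 0.5 * exp((10 - vs) / 40)
  m' = m_alpha * (1 - m) - m_beta * m
  h' = h_alpha * (1 - h) - h_beta * h
  n' = n_alpha * (1 - n) - n_beta * n
  gE' = -gE / tauE
  gI' = -gI / tauI
  V' = (gL * (EL - V) + gNa * m^3 * h * (ENa - V) + gK * n^4 * (EK - V) + gE * (EE - V) + gI * (EI - V)) / C
  V = EL + 5 - 10 * uniform() @ $init
  m = m_alpha / (m_alpha + m_beta) @ $init
  h = h_alpha / (h_alpha + h_beta) @ $init
  n = n_alpha / (n_alpha + n_beta) @ $init
  $ref brette2007benchmarks

part BretteSynapse
  connect A = BretteNeuron, B = BretteNeuron
  w = 6
  Erev = 0
  tau = 5
  th = -20
  $p = 0.02
  g' = -g / tau
  g = g + w @ crossed(A.V, th)
  B.V' = g * (Erev - B.V) / B.C
  $ref brette2007benchmarks

part Spiker
  rate = %g
  active = $t < %g
  fired = (uniform() < rate * $dt) * active

part InputSynapse
  connect A = Spiker, B = BretteNeuron
  w = %g
  Erev = 0
  tau = 5
  g' = -g / tau
  $p = 0.02
  g = g + w @ crossed(A.fired, 0.5)
  B.V' = g * (Erev - B.V) / B.C

part EINetwork
  include n = BretteNeuron
  include sp = Spiker
  include Esyn = BretteSynapse
  include Isyn = BretteSynapse
  include inp = InputSynapse
  we = %g
  wi = %g
  pconn = %g
  n.$n = %d
  sp.$n = %d
  Esyn.$p = (A.$index < 0.8 * A.$n) * pconn
  Esyn.w = we
  Isyn.$p = (A.$index >= 0.8 * A.$n) * pconn
  Isyn.w = wi
  Isyn.Erev = -80
  Isyn.tau = 10
  $meta composition = 80%% excitatory, 20%% inhibitory by source index
",
    kick_rate, kick_ms, w_input, we, wi, pconn, as.integer(N), as.integer(n_spikers))
  repo <- parse_model_text(src)
  stopifnot(length(validate_repository(repo)) == 0L)
  repo
}

#' Build the growth-cone arborization model
#'
#' A `GrowthCone` instance draws one uniform variate per step and,
#' against cumulative probability bands, elongates (splits into a
#' stable `Segment` plus a cone), branches (segment plus two cones),
#' differentiates (becomes a segment), or dies.  Segments are inert.
#' With branching probability b and removal probabilities d (death)
#' and f (differentiation), the expected cone count after t steps is
#' `n0 * (1 + b - d - f)^t`.
#'
#' @param rates List with per-step event probabilities `elongate`,
#'   `branch`, `differentiate`, `death` (sum <= 1).
#' @param n0 Initial number of growth cones.
#' @return A validated `"part_repository"` with model entry
#'   `DendriteModel`.
#' @export
build_growth_cone_fixture <- function(rates = list(elongate = 0.2, branch = 0.05,
                                                   differentiate = 0.01, death = 0.01),
                                      n0 = 1) {
  r <- rates
  stopifnot(all(unlist(r) >= 0), sum(unlist(r)) <= 1)
  events <- .band_conditions("u", c(r$elongate, r$branch, r$differentiate, r$death),
                             c("[Segment, GrowthCone]",
                               "[Segment, GrowthCone, GrowthCone]",
                               "[Segment]", "[]"))
  src <- sprintf("
model DendriteModel

part GrowthCone
  u = uniform()
%s  $meta role = motile dendrite tip

part Segment
  $meta role = stable dendrite compartment

part DendriteModel
  include cone = GrowthCone
  include seg = Segment
  cone.$n = %d
  seg.$n = 0
", events, as.integer(n0))
  repo <- parse_model_text(src)
  stopifnot(length(validate_repository(repo)) == 0L)
  repo
}

# Disjoint two-sided condition bands over one per-step uniform draw:
# mutually exclusive regardless of equation ordering, with zero-width
# bands (zero-probability events) omitted entirely.
.band_conditions <- function(var, probs, outcomes) {
  cum <- cumsum(c(0, probs))
  lines <- character(0)
  for (i in seq_along(probs)) {
    if (probs[[i]] <= 0) next
    lines <- c(lines, sprintf("  $type = %s @ %s >= %.10g && %s < %.10g\n",
                              outcomes[[i]], var, cum[[i]], var, cum[[i + 1L]]))
  }
  paste(lines, collapse = "")
}

#' Per-step stem-cell lineage rates
#'
#' @param p_asym Radial-glia asymmetric-division probability.
#' @param p_sym Progenitor symmetric-division probability.
#' @param p_diff Progenitor differentiation probability.
#' @param p_death Progenitor death probability.
#' @return Named list; progenitor probabilities must sum to <= 1.
#' @export
lineage_rates <- function(p_asym = 0.05, p_sym = 0.1, p_diff = 0.05, p_death = 0.05) {
  r <- list(p_asym = p_asym, p_sym = p_sym, p_diff = p_diff, p_death = p_death)
  stopifnot(all(unlist(r) >= 0), all(unlist(r) <= 1),
            p_sym + p_diff + p_death <= 1)
  r
}

#' Build the adult-neurogenesis lineage model
#'
#' A radial glial cell (RGC) divides asymmetrically, producing a copy
#' of itself plus a neural progenitor (NPC); progenitors divide
#' symmetrically, differentiate into granule cells, or die, each as a
#' per-step probability.  Expected counts follow the linear recursion
#' `v_{t+1} = v_t M` with transition matrix M determined by the rates.
#'
#' @param rates List from [lineage_rates()].
#' @param n_rgc Initial radial-glia count.
#' @return A validated `"part_repository"` with model entry
#'   `NeurogenesisModel`.
#' @export
build_neurogenesis_fixture <- function(rates = lineage_rates(), n_rgc = 10) {
  r <- rates
  rgc_events <- .band_conditions("u", r$p_asym, "[RadialGlia, Progenitor]")
  npc_events <- .band_conditions("u", c(r$p_sym, r$p_diff, r$p_death),
                                 c("[Progenitor, Progenitor]", "[GranuleCell]", "[]"))
  src <- sprintf("
model NeurogenesisModel

part RadialGlia
  u = uniform()
%s  $meta role = primordial stem cell

part Progenitor
  u = uniform()
%s  $meta role = transit-amplifying cell

part GranuleCell
  $meta role = differentiated neuron

part NeurogenesisModel
  include rgc = RadialGlia
  include npc = Progenitor
  include gc = GranuleCell
  rgc.$n = %d
  npc.$n = 0
  gc.$n = 0
", rgc_events, npc_events, as.integer(n_rgc))
  repo <- parse_model_text(src)
  stopifnot(length(validate_repository(repo)) == 0L)
  repo
}

#' Path to a packaged fixture file
#'
#' @param name File name under the package's `extdata` directory, e.g.
#'   `"hh_cable.part.txt"`; with no argument, lists available fixtures.
#' @return File path, or a character vector of available names.
#' @export
fixture_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "partsim")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no packaged fixture '", name, "'", call. = FALSE)
  path
}
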