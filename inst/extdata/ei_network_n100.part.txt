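model EINetwork
part BretteNeuron
  C = 200
  EE = 0
  EI = -80
  EK = -90
  EL = -65
  ENa = 50
  gE' = -gE / tauE
  gI' = -gI / tauI
  gK = 1800
  gL = 10
  gNa = 6000
  h = h_alpha / (h_alpha + h_beta) @ $init
  h' = h_alpha * (1 - h) - h_beta * h
  h_alpha = 0.128 * exp((17 - vs) / 18)
  h_beta = 4 / (1 + exp((40 - vs) / 5))
  m = m_alpha / (m_alpha + m_beta) @ $init
  m' = m_alpha * (1 - m) - m_beta * m
  m_alpha = 0.32 * (13 - vs) / (exp((13 - vs) / 4) - 1 + 1e-09)
  m_beta = 0.28 * (vs - 40) / (exp((vs - 40) / 5) - 1 + 1e-09)
  n = n_alpha / (n_alpha + n_beta) @ $init
  n' = n_alpha * (1 - n) - n_beta * n
  n_alpha = 0.032 * (15 - vs) / (exp((15 - vs) / 5) - 1 + 1e-09)
  n_beta = 0.5 * exp((10 - vs) / 40)
  tauE = 5
  tauI = 10
  V = EL + 5 - 10 * uniform() @ $init
  V' = (gL * (EL - V) + gNa * m ^ 3 * h * (ENa - V) + gK * n ^ 4 * (EK - V) + gE * (EE - V) + gI * (EI - V)) / C
  vs = V - VT
  VT = -63
  $ref brette2007benchmarks
part BretteSynapse
  connect A = BretteNeuron, B = BretteNeuron
  $p = 0.02
  B.V' = g * (Erev - B.V) / B.C
  Erev = 0
  g = g + w @ crossed(A.V, th)
  g' = -g / tau
  tau = 5
  th = -20
  w = 6
  $ref brette2007benchmarks
part EINetwork
  include Esyn = BretteSynapse
  include inp = InputSynapse
  include Isyn = BretteSynapse
  include n = BretteNeuron
  include sp = Spiker
  Esyn.$p = (A.$index < 0.8 * A.$n) * pconn
  Esyn.w = we
  Isyn.$p = (A.$index >= 0.8 * A.$n) * pconn
  Isyn.Erev = -80
  Isyn.tau = 10
  Isyn.w = wi
  n.$n = 100
  pconn = 0.1
  sp.$n = 5
  we = 6
  wi = 67
  $meta composition = 80% excitatory, 20% inhibitory by source index
part InputSynapse
  connect A = Spiker, B = BretteNeuron
  $p = 0.02
  B.V' = g * (Erev - B.V) / B.C
  Erev = 0
  g = g + w @ crossed(A.fired, 0.5)
  g' = -g / tau
  tau = 5
  w = 30
part Spiker
  active = $t < 50
  fired = (uniform() < rate * $dt) * active
  rate = 0.04
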