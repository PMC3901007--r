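model CableModel
part AbstractChannel
  Erev = 0
  gbar = 0
  I = gbar * open * (Erev - V)
  open = 1
  $meta role = ionic conductance template
part CableCoupling
  connect A = HHCompartment, B = HHCompartment
  $p = A.$index + 1 == B.$index
  A.V' = gr * (B.V - A.V) / A.C
  B.V' = gr * (A.V - B.V) / B.C
  gr = 0.3
part CableModel
  include cable = CableCoupling
  include comp = HHCompartment
  area = 100
  comp.$n = 3
  comp.Iinj = inj * 100 / area * (comp.$index == 0) * ($t >= 1)
  inj = 10
  $meta description = multicompartment cable with active HH membrane
part HHCompartment : PassiveCompartment
  include K = KChannel
  include Na = NaChannel
  V' = (gleak * (Eleak - V) + Na.I + K.I + Iinj) / C
part KChannel : AbstractChannel
  Erev = -77
  gbar = 36
  n = n_alpha / (n_alpha + n_beta) @ $init
  n' = n_alpha * (1 - n) - n_beta * n
  n_alpha = 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10) + 1e-09)
  n_beta = 0.125 * exp(-(V + 65) / 80)
  open = n ^ 4
part NaChannel : AbstractChannel
  Erev = 50
  gbar = 120
  h = h_alpha / (h_alpha + h_beta) @ $init
  h' = h_alpha * (1 - h) - h_beta * h
  h_alpha = 0.07 * exp(-(V + 65) / 20)
  h_beta = 1 / (1 + exp(-(V + 35) / 10))
  m = m_alpha / (m_alpha + m_beta) @ $init
  m' = m_alpha * (1 - m) - m_beta * m
  m_alpha = 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10) + 1e-09)
  m_beta = 4 * exp(-(V + 65) / 18)
  open = m ^ 3 * h
part PassiveCompartment
  C = 1
  Eleak = -54.387
  gleak = 0.3
  Iinj = 0
  V = -65 @ $init
  V' = (gleak * (Eleak - V) + Iinj) / C
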