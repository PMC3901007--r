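model NeurogenesisModel
part GranuleCell
  $meta role = differentiated neuron
part NeurogenesisModel
  include gc = GranuleCell
  include npc = Progenitor
  include rgc = RadialGlia
  gc.$n = 0
  npc.$n = 0
  rgc.$n = 10
part Progenitor
  $type = [Progenitor, Progenitor] @ u >= 0 && u < 0.1
  $type = [GranuleCell] @ u >= 0.1 && u < 0.15
  $type = [] @ u >= 0.15 && u < 0.2
  u = uniform()
  $meta role = transit-amplifying cell
part RadialGlia
  $type = [RadialGlia, Progenitor] @ u >= 0 && u < 0.05
  u = uniform()
  $meta role = primordial stem cell
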