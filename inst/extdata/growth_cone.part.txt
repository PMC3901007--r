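model DendriteModel
part DendriteModel
  include cone = GrowthCone
  include seg = Segment
  cone.$n = 1
  seg.$n = 0
part GrowthCone
  $type = [Segment, GrowthCone] @ u >= 0 && u < 0.2
  $type = [Segment, GrowthCone, GrowthCone] @ u >= 0.2 && u < 0.25
  $type = [Segment] @ u >= 0.25 && u < 0.26
  $type = [] @ u >= 0.26 && u < 0.27
  u = uniform()
  $meta role = motile dendrite tip
part Segment
  $meta role = stable dendrite compartment
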