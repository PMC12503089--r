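# Example study configuration: no pre-existing antibodies, peak of 10 units
# expected 30 days after immunization, plateau of 1 unit from day 365.
info:
  A0: 0
  tmax: 30
  Amax: 10
  tplat: 365
  Aplat: 1
# Optional; these are the defaults.
error:
  sigma: 0.25
  rho: 0.73
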