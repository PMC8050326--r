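# Demo pipeline configuration: a paper-like 90 x 90 m / 10 m survey with
# a reduced attribute set and a coarser kriging raster for speed.
seed: 1
survey:
  extent: 90
  spacing: 10
  attributes: [FCO2, SOM, Macro, AFPS, TPV, Micro]
variography:
  kinds: [spherical, exponential]
  weighting: npairs
kriging:
  cell_size: 3
regions:
  attribute: FCO2
  low_band: [1.9, 2.7]
  high_band: [2.9, 4.2]
comparison:
  alpha: 0.01
  n_per_group: 9
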