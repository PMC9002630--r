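Embedded plain-text data files
==============================

repulsion66.csv, repulsion168.csv, repulsion616.csv
  {alpha, beta} crystallite angle pairs (radians) generated by the package's
  own electrostatic-repulsion optimizer (repulsion_points(), seed = 42,
  400 iterations), stored so that the common powder-set sizes are
  deterministic and instantaneous to load.

flopsy16_element_synthetic.tsv
  SYNTHETIC stand-in for the FLOPSY base composite-pulse element. The
  verbatim flip-angle table of the original publication is not
  redistributed here; this file reproduces the documented aggregate
  structure only (9 palindromic pulses, strictly alternating +x/-x phases,
  total flip 2120.04 degrees = 23.556 tau_90 per element, 8 elements =
  188.448 tau_90 per cycle). Replace via flopsy16(element_file = ...) to
  use the original element.
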