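# nn_lite nearest-neighbor parameter set
# Energies in kcal/mol at 37 C.  Stacking entries are "stack <outer> <inner>"
# where a pair XY means 5'-X paired with 3'-Y and the inner pair is read in
# the same orientation.  Loop entries are "<type> <size> <energy>" with size
# the number of unpaired nucleotides in the loop; sizes beyond the table are
# extrapolated as E(max) + lxc * ln(size/max).
# "multiloop a b c" gives the affine multiloop model: a per closed multiloop,
# b per branch (the closing pair counts as a branch), c per unpaired
# nucleotide inside the loop.
multiloop 3.4 0.4 0.0
lxc 1.079
stack AU AU -0.9
stack AU UA -1.1
stack AU GC -2.2
stack AU CG -2.1
stack AU GU -0.6
stack AU UG -1.4
stack UA AU -1.3
stack UA UA -0.9
stack UA GC -2.4
stack UA CG -2.1
stack UA GU -1.0
stack UA UG -1.3
stack GC AU -2.1
stack GC UA -2.2
stack GC GC -3.3
stack GC CG -2.4
stack GC GU -1.4
stack GC UG -1.5
stack CG AU -2.4
stack CG UA -2.1
stack CG GC -3.4
stack CG CG -3.3
stack CG GU -1.5
stack CG UG -2.5
stack GU AU -1.3
stack GU UA -1.4
stack GU GC -2.5
stack GU CG -2.1
stack GU GU -0.5
stack GU UG 1.3
stack UG AU -1.0
stack UG UA -0.6
stack UG GC -2.1
stack UG CG -1.4
stack UG GU 0.3
stack UG UG -0.5
hairpin 3 5.4
hairpin 4 5.6
hairpin 5 5.7
hairpin 6 5.4
hairpin 7 6.0
hairpin 8 5.5
hairpin 9 6.4
hairpin 10 6.51
hairpin 11 6.62
hairpin 12 6.71
hairpin 13 6.80
hairpin 14 6.88
hairpin 15 6.95
hairpin 16 7.02
hairpin 17 7.09
hairpin 18 7.15
hairpin 19 7.21
hairpin 20 7.26
hairpin 21 7.31
hairpin 22 7.36
hairpin 23 7.41
hairpin 24 7.46
hairpin 25 7.50
hairpin 26 7.55
hairpin 27 7.59
hairpin 28 7.63
hairpin 29 7.66
hairpin 30 7.70
bulge 1 3.8
bulge 2 2.8
bulge 3 3.2
bulge 4 3.6
bulge 5 4.0
bulge 6 4.4
bulge 7 4.57
bulge 8 4.71
bulge 9 4.84
bulge 10 4.95
bulge 11 5.05
bulge 12 5.15
bulge 13 5.23
bulge 14 5.31
bulge 15 5.39
bulge 16 5.46
bulge 17 5.52
bulge 18 5.59
bulge 19 5.64
bulge 20 5.70
bulge 21 5.75
bulge 22 5.80
bulge 23 5.85
bulge 24 5.90
bulge 25 5.94
bulge 26 5.98
bulge 27 6.02
bulge 28 6.06
bulge 29 6.10
bulge 30 6.14
internal 2 4.1
internal 3 5.1
internal 4 4.9
internal 5 5.3
internal 6 5.7
internal 7 5.87
internal 8 6.01
internal 9 6.14
internal 10 6.25
internal 11 6.35
internal 12 6.45
internal 13 6.53
internal 14 6.61
internal 15 6.69
internal 16 6.76
internal 17 6.82
internal 18 6.89
internal 19 6.94
internal 20 7.00
internal 21 7.05
internal 22 7.10
internal 23 7.15
internal 24 7.20
internal 25 7.24
internal 26 7.28
internal 27 7.32
internal 28 7.36
internal 29 7.40
internal 30 7.44
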