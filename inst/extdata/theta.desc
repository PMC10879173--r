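# Refined theta-ribozyme motif: tightened length ranges, identity
# constraints at highly conserved (>97%) positions, and one additional
# degree of freedom (R) at the last position of the J4/2 junction.
# The catalytic cytosine is the first position of J4/2.
name: theta
order: p1 j12 p2 p3 l3 p3' p1' j14 p4 l4 p4' j42 p2'
p1   6:6  NNNAGC
j12  2:3  -
p2   5:5  NNNNN
p3   3:3  GCG
l3   5:8  NNCCCNNN
p3'  3:3  NNN
p1'  6:6  GCTNNN
j14  1:2  -
p4   2:3  NNN
l4   2:3  -
p4'  2:3  NNN
j42  4:4  CNNR
p2'  5:5  NNNNN
catalytic: j42 0
cleavage: p1
nratio: 0.1
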