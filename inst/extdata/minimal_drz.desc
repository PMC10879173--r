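# Minimal HDV-like delta ribozyme search motif (loose starting motif).
#
# Element order 5'->3' along the sequence; primed ids are helix 3'
# strands, so p2/p2' is the pseudoknot closing the fold (its 3' strand is
# the last element) and p1.1-like pairing is not modelled separately.
# G1, the cleavage site, is the first nucleotide of the P1 5' strand.
name: minimal_drz
order: p1 j12 p2 p3 l3 p3' p1' j14 p4 l4 p4' j42 p2'
p1   6:6  NNNNNN
j12  1:4  -
p2   5:5  NNNNN
p3   3:3  NNN
l3   4:8  -
p3'  3:3  NNN
p1'  6:6  NNNNNN
j14  1:3  -
p4   2:3  NNN
l4   2:4  -
p4'  2:3  NNN
j42  4:5  CNNNN
p2'  5:5  NNNNN
catalytic: j42 0
cleavage: p1
nratio: 0.1
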