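# cellulose: unbranched D-glucose chain, consecutive monomers flipped 180 deg
alphabet: m, g, E, C
structure: m = Dglucose sphere
binding: g
end: E
global: t_max = 5
axiom: C(grow, Dglucose, 0, EMPTY)
rule p1: C(grow,T,t,r) : r != EMPTY -> m g C(grow,T,0,EMPTY) : 1.0
rule p2: C(grow,T,t,r) : t > t_max -> E : 1.0
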