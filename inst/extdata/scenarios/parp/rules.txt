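# poly-ADP-ribose: branched chain; p1 carries the branch decision
alphabet: m, g, b, E, C
structure: m = NAD sphere
binding: g, b
end: E
global: t_max = 5
axiom: C(grow, NAD, 0, EMPTY)
rule p1: C(grow,T,t,r) : r != EMPTY -> m C(branch,T,0,EMPTY) g C(grow,T,0,EMPTY) : 0.05
rule p2: C(grow,T,t,r) : r != EMPTY -> m g C(grow,T,0,EMPTY) : 1.0
rule p3: C(branch,T,t,r) : r != EMPTY -> b m g C(grow,T,0,EMPTY) E : 1.0
rule p4: C(grow,T,t,r) : t > t_max -> nil : 1.0
rule p5: C(branch,T,t,r) : t > t_max -> nil : 1.0
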