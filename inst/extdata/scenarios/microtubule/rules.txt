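# microtubule: helical dimer lattice, 13 dimers per turn
alphabet: a, b, v, h, E, C
structure: a = alpha_tubulin sphere, b = beta_tubulin sphere
binding: v, h
end: E
agents: tubulin
global: t_max = 5
axiom: C(grow, tubulin, 0, EMPTY)
rule p1: C(grow,T,t,r) : r != EMPTY -> a v b h C(grow,T,0,EMPTY) : 1.0
rule p2: C(grow,T,t,r) : t > t_max -> E : 1.0
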