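# synthetic showcase: helical main branch, side branches, terminal star
alphabet: s, c, y, g, l, b, E, C, u1, u2, u3, u4, u5
structure: s = sphereunit sphere, c = cubeunit cube, y = cylunit cylinder
binding: g, l, b, u1, u2, u3, u4, u5
end: E
global: t_max = 5
axiom: C(grow, sphereunit, 0, EMPTY)
rule p1: C(grow,T,t,r) : r != EMPTY -> s C(branch,T,0,EMPTY) g C(grow,T,0,EMPTY) : 0.1
rule p2: C(grow,T,t,r) : r != EMPTY -> s g C(grow,T,0,EMPTY) : 1.0
rule p3: C(branch,T,t,r) : r != EMPTY -> b s g C(sidegrow,T,0,EMPTY) E : 1.0
rule p4: C(sidegrow,T,t,r) : r != EMPTY -> s g C(sidegrow,T,0,EMPTY) : 1.0
rule p5: C(sidegrow,T,t,r) : t > t_max -> nil : 1.0
rule p6: C(branch,T,t,r) : t > t_max -> nil : 1.0
rule p7: C(grow,T,t,r) : t > t_max -> u1 c C(star,cylunit,0,EMPTY) E u2 c C(star,cylunit,0,EMPTY) E u3 c C(star,cylunit,0,EMPTY) E u4 c C(star,cylunit,0,EMPTY) E u5 c C(star,cylunit,0,EMPTY) E : 1.0
rule p8: C(star,cylunit,t,r) : r != EMPTY -> l y C(star,cubeunit,0,EMPTY) : 1.0
rule p9: C(star,cubeunit,t,r) : r != EMPTY -> l c C(star,cylunit,0,EMPTY) : 1.0
rule p10: C(star,T,t,r) : t > t_max -> nil : 1.0
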