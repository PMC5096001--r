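// generic bacterial central carbon metabolism: glycolysis (lumped),
// pentose phosphate pathway, TCA cycle, glyoxylate shunt, anaplerotic
// carboxylation, acetate overflow, biomass drain and ATP maintenance.
// Representative atom transitions and cofactor stoichiometries; the
// maintenance reaction ships disabled (bounds 0) and is opened by the
// energy-mode analyses.
# MET GLCx 6 external substrate
# MET G6P 6 balanced
# MET F6P 6 balanced
# MET T3P 3 balanced
# MET PEP 3 balanced
# MET PYR 3 balanced
# MET ACA 2 balanced
# MET OAA 4 balanced
# MET ICT 6 balanced
# MET AKG 5 balanced
# MET SUC 4 balanced symmetric
# MET MAL 4 balanced
# MET GLX 2 balanced
# MET Ru5P 5 balanced
# MET R5P 5 balanced
# MET X5P 5 balanced
# MET S7P 7 balanced
# MET E4P 4 balanced
# MET CO2 1 balanced
# MET ACEx 2 external
# MET CO2x 1 external
# MET BIOMASS 0 external
vupt: GLCx (abcdef) -> G6P (abcdef) | ATP:-1 @ uptake
vpgi: G6P (abcdef) <-> F6P (abcdef)
vpfk: F6P (abcdef) -> T3P (cba) + T3P (def) | ATP:-1
vgap: T3P (abc) -> PEP (abc) | ATP:1 NADH:1
vpk: PEP (abc) -> PYR (abc) | ATP:1
vpdh: PYR (abc) -> ACA (bc) + CO2 (a) | NADH:1
vcs: OAA (abcd) + ACA (ef) -> ICT (dcbafe)
vidh: ICT (abcdef) -> AKG (abcde) + CO2 (f) | NADPH:1
vakgdh: AKG (abcde) -> SUC (bcde) + CO2 (a) | ATP:1 NADH:1
vsdh: SUC (abcd) <-> MAL (abcd) | FADH2:1
vmdh: MAL (abcd) <-> OAA (abcd) | NADH:1
vicl: ICT (abcdef) -> GLX (ab) + SUC (cdef)
vms: GLX (ab) + ACA (cd) -> MAL (abdc)
vppc: PEP (abc) + CO2 (d) -> OAA (abcd)
vzwf: G6P (abcdef) -> Ru5P (bcdef) + CO2 (a) | NADPH:2
vrpi: Ru5P (abcde) <-> R5P (abcde)
vrpe: Ru5P (abcde) <-> X5P (abcde)
vtkt1: X5P (abcde) + R5P (fghij) <-> S7P (abfghij) + T3P (cde)
vtal: S7P (abcdefg) + T3P (hij) <-> F6P (abchij) + E4P (defg)
vtkt2: X5P (abcde) + E4P (fghi) <-> F6P (abfghi) + T3P (cde)
vace: ACA (ab) -> ACEx (ab) | ATP:1 @ excretion
vco2: CO2 (a) -> CO2x (a) @ excretion
vbio: 0.205 G6P () + 0.071 F6P () + 0.898 R5P () + 0.361 E4P () + 0.129 T3P () + 1.496 PEP () + 2.833 PYR () + 3.748 ACA () + 1.787 OAA () + 1.079 AKG () -> BIOMASS () | ATP:-41.3 NADPH:-18.2 NADH:3.5 @ biomass
vatpm: -> | ATP:-1 @ maintenance [0, 0]
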