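// 10-metabolite cyclic fixture: TCA-like cycle fed by a 2-carbon and a
// 3-carbon substrate, with a cleavage (c2, c3, c6), a condensation (c1, c7),
// a reversible step (c4) and a rotationally symmetric metabolite (SUC).
// Small enough for full-isotopomer cross-checks.
# MET S2 2 external substrate
# MET S3 3 external substrate
# MET ACA 2 balanced
# MET OAA 4 balanced
# MET CIT 6 balanced
# MET AKG 5 balanced
# MET SUC 4 balanced symmetric
# MET MAL 4 balanced
# MET PYR 3 balanced
# MET CO2 1 balanced
# MET AKGx 5 external
# MET CO2x 1 external
u1: S2 (ab) -> ACA (ab) @ uptake
u2: S3 (abc) -> PYR (abc) @ uptake
c1: OAA (abcd) + ACA (ef) -> CIT (dcbafe)
c2: CIT (abcdef) -> AKG (abcde) + CO2 (f)
c3: AKG (abcde) -> SUC (bcde) + CO2 (a)
c4: SUC (abcd) <-> MAL (abcd)
c5: MAL (abcd) -> OAA (abcd)
c6: MAL (abcd) -> PYR (abc) + CO2 (d)
c7: PYR (abc) + CO2 (d) -> OAA (abcd)
e1: AKG (abcde) -> AKGx (abcde) @ excretion
e2: CO2 (a) -> CO2x (a) @ excretion
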