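// branched toy network: 3-carbon substrate split over two cleavage routes
// with different positional fates (C gets backbone 1-2 via v2 but 2-3 via
// v3), CO2 release, and a reversible isomerization C <-> D
# MET S 3 external substrate
# MET B 3 balanced
# MET C 2 balanced
# MET D 2 balanced
# MET CO2 1 balanced
# MET Dext 2 external
# MET CO2ext 1 external
v1: S (abc) -> B (abc) @ uptake
v2: B (abc) -> C (ab) + CO2 (c) | ATP:2 NADH:1
v3: B (abc) -> C (bc) + CO2 (a) | ATP:1 NADPH:1
v4: C (ab) <-> D (ab)
v5: D (ab) -> Dext (ab) | ATP:-2 @ excretion
v6: CO2 (a) -> CO2ext (a) @ excretion
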