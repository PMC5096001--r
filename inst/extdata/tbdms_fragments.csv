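fragment_id,metabolite,backbone_atoms,extra_formula,notes
Gly_M-57,GLY,1 2,C8H24NO2Si2,full backbone
Gly_M-159,GLY,2,C6H18NSi,loses carbon 1
Ala_M-57,ALA,1 2 3,C8H26NO2Si2,full backbone
Ala_M-159,ALA,2 3,C6H20NSi,loses carbon 1
Ala_f302,ALA,1 2,C11H28NOSi2,carbons 1-2
Val_M-57,VAL,1 2 3 4 5,C8H30NO2Si2,full backbone
Val_M-159,VAL,2 3 4 5,C6H24NSi,loses carbon 1
Ser_M-57,SER,1 2 3,C14H40NO3Si3,full backbone
Ser_M-159,SER,2 3,C12H34NOSi2,loses carbon 1
Asp_M-57,ASP,1 2 3 4,C14H40NO4Si3,full backbone
Asp_M-159,ASP,2 3 4,C12H34NO2Si2,loses carbon 1
Glu_M-57,GLU,1 2 3 4 5,C14H42NO4Si3,full backbone
Glu_M-159,GLU,2 3 4 5,C12H36NO2Si2,loses carbon 1
Phe_M-57,PHE,1 2 3 4 5 6 7 8 9,C8H30NO2Si2,full backbone
Phe_M-159,PHE,2 3 4 5 6 7 8 9,C6H24NSi,loses carbon 1
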