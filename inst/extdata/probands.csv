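proband_id,sex,age_years,exon,nucleotide_change,protein_change,allele_state,stage_le,stage_re,bcva_le,bcva_re,family_segregation,second_nucleotide_change,second_protein_change
P1,M,50,ex2,c.5C>T,p.(Thr2Ile),HET,5,5,0.1,0.4,no,NA,NA
P2,F,42,ex2,c.11C>T,p.(Thr4Ile),HET,2,2,0,0,no,NA,NA
P3,F,13,ex2,c.11C>T,p.(Thr4Ile),HET,1,1,0.1,0.1,yes,NA,NA
P4,M,27,ex2,c.26T>G,p.(Val9Gly),HET,2,2,0,0.6,yes,NA,NA
P5,F,34,ex2,c.44G>A,p.(Gly15Asp),HET,NA,NA,NA,NA,no,NA,NA
P6,M,22,ex2,c.44G>A,p.(Gly15Asp),HET,3,4,0,0.2,no,NA,NA
P7,F,13,ex2,c.44G>A,p.(Gly15Asp),HET,0,3,0,0.22,no,NA,NA
P8,M,56,ex2,c.47C>T,p.(Ser16Phe),HET,2,2,0.1,0.7,yes,NA,NA
P9,F,23,ex2,c.74G>A,p.(Arg25Gln),HET,4,2,0.5,0,no,NA,NA
P10,F,47,ex1,c.80G>C,p.(Ser27Thr),HET,3,4,0.1,0.2,no,NA,NA
P11,F,55,ex2,c.80G>C,p.(Ser27Thr),HET,2,2,NA,NA,yes,NA,NA
P12,F,52,ex2,c.80G>C,p.(Ser27Thr),HET,3,3,0.7,1,no,NA,NA
P13,M,10,ex2,c.86A>G,p.(Tyr29Cys),HET,4,4,0,0,yes,NA,NA
P14,F,27,ex4,c.274C>T,p.(Arg92Cys),HOM,NA,NA,NA,NA,no,NA,NA
P15,M,42,ex4,c.278G>C,p.(Trp93Ser),HET,NA,NA,NA,NA,no,NA,NA
P16,M,70,ex4,c.301C>A,p.(Pro101Thr),HET,4,3,0.5,0,yes,NA,NA
P17,M,26,ex4,c.324C>G,p.(Ser108Arg),HET,2,2,0.1,1,no,NA,NA
P18,M,46,ex5,c.535A>G,p.(Asn179Asp),HET,1,2,0.3,0.3,no,NA,NA
P19,F,13,ex5,c.544T>C,p.(Trp182Arg),HET,4,4,NA,NA,no,NA,NA
P20,M,19,ex5,c.598C>T,p.(Arg200*),HET,NA,NA,NA,NA,yes,c.728C>A,p.(Ala243Glu)
P21,F,25,ex6,c.652C>T,p.(Arg218Cys),HET,2,2,0.1,0,yes,NA,NA
P22,F,13,ex6,c.652C>T,p.(Arg218Cys),HET,0,3,0,0.17,no,NA,NA
P23,M,14,ex6,c.652C>T,p.(Arg218Cys),HET,2,2,0.4,0,no,NA,NA
P24,M,42,ex6,c.652C>A,p.(Arg218Ser),HET,3,3,0.5,0.4,no,NA,NA
P25,M,54,ex5,c.695T>A,p.(Ile232Asn),HET,3,3,0.6,0.8,no,NA,NA
P26,M,17,ex6,c.703G>T,p.(Val235Leu),HET,3,3,0.1,0.1,no,NA,NA
P27,F,51,ex7,c.727G>A,p.(Ala243Thr),HET,2,2,1,1,yes,NA,NA
P28,M,49,ex7,c.728C>T,p.(Ala243Val),HET,3,3,0.1,0,no,NA,NA
P29,F,43,ex7,c.728C>T,p.(Ala243Val),HET,3,2,0.2,0.2,yes,NA,NA
P30,F,50,ex7,c.728C>T,p.(Ala243Val),HET,NA,NA,NA,NA,yes,NA,NA
P31,M,9,ex8,c.874G>C,p.(Glu292Gln),HET,2,2,1,1,yes,NA,NA
P32,M,39,ex8,c.888C>G,p.(Asn296Lys),HET,3,3,0.1,0.3,no,NA,NA
P33,F,41,ex8,c.888C>A,p.(Asn296Lys),HET,2,2,0.3,0.3,no,NA,NA
P34,M,10,ex8,c.893T>G,p.(Phe298Cys),HET,NA,NA,NA,NA,no,NA,NA
P35,M,53,ex8,c.893T>G,p.(Phe298Cys),HET,NA,NA,NA,NA,no,NA,NA
P36,M,21,ex8,c.903T>G,p.(Asp301Glu),HET,NA,NA,0,0.6,yes,NA,NA
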