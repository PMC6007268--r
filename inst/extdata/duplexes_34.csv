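# 34-duplex optical melting corpus: top strands 5'->3', number of melts,
# and the source's complementarity annotation (TRUE = annotated with '/',
# i.e. melted against the fully complementary separate strand).
duplex_id,top_strand,n_melts,annotated_non_self_comp,reference
dx01,GACUCAG,9,TRUE,xia1998
dx02,GAGGAG,12,TRUE,xia1998
dx03,GAGUGAG,7,TRUE,xia1998
dx04,GCACG,6,TRUE,xia1998
dx05,GCUCG,6,TRUE,xia1998
dx06,GGCUUCAA,9,TRUE,xia1998
dx07,GUCACUG,9,TRUE,xia1998
dx08,GUGUCG,8,TRUE,xia1998
dx09,UAUGCAUA,7,FALSE,xia1998
dx10,UCAGACU,15,TRUE,xia1998
dx11,UCAUGA,6,FALSE,xia1998
dx12,UCGCU,5,TRUE,xia1998
dx13,UCUAUAGA,10,FALSE,xia1998
dx14,UGACAGU,9,TRUE,xia1998
dx15,UGAUCA,13,FALSE,xia1998
dx16,UGCGU,3,TRUE,xia1998
dx17,UUCCGGAA,9,FALSE,xia1998
dx18,UUGCGCAA,9,FALSE,xia1998
dx19,UUGGCCAA,7,FALSE,xia1998
dx20,UUGUACAA,9,FALSE,xia1998
dx21,CAGUCAGU,7,TRUE,kierzek2006
dx22,UCAAUUAGU,7,TRUE,kierzek2006
dx23,UCACUGAGU,9,TRUE,kierzek2006
dx24,UCAGUCAG,11,TRUE,kierzek2006
dx25,UCAGUCAGU,8,TRUE,kierzek2006
dx26,UCAUUAAGU,8,TRUE,kierzek2006
dx27,CACAGCAC,7,TRUE,rauzan2013
dx28,CACGGCUC,7,TRUE,rauzan2013
dx29,UUAUCGAUAA,8,TRUE,nguyen2015
dx30,AUCGGUA,11,TRUE,unpublished
dx31,UUGACCAU,9,TRUE,unpublished
dx32,AACUAGUU,6,FALSE,unpublished
dx33,AGUAUACU,6,FALSE,unpublished
dx34,UAGAUCUA,13,FALSE,unpublished
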