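sample_id,breed,age_years,sex,location,treatment,dfi_days,ost_days
dog01,Great Dane,9,SF,L distal radius,Sx/Carboplatin,340,420
dog02,Saint Bernard,6,SF,R distal radius,Sx/Carboplatin,,
dog03,Doberman,5,SF,L distal radius,Sx/Carboplatin,308,316
dog04,Pitbull Mix,7,NM,L distal radius,Sx/Carboplatin,688,688
dog05,German Shepherd,7,SF,R distal radius,Sx/Carboplatin,676,783
dog06,Saint Bernard,5,NM,L distal radius,Sx/Carboplatin and doxorubicin (rescue),58,81
dog07,Newfoundland,5,SF,R distal radius,Sx/Carboplatin and doxorubicin (rescue),70,165
dog08,Doberman,7,NM,L distal radius,Sx/Carboplatin,62,196
dog09,Mixed,10,NM,R distal radius,Sx/Carboplatin and doxorubicin; dasatinib (rescue),88,372
dog10,Golden Retriever,9,NM,R proximal humerus,Sx/Carboplatin and doxorubicin; listeria vaccine (rescue),61,131
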