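product,atc_class,route,originator,rating_alternative,rating_disease,rating_susceptibility,rating_costs,rating_n_patients,published_overall
BCG instillation,L,parenteral,TRUE,2,3,3,2,2,72
Risperidone orodispersible tablet,N,oral,TRUE,2,3,3,3,1,54
Epinephrine injection,C,parenteral,TRUE,2,3,2,2,2,48
Methoxy polyethylene glycol-epoetin beta injection,B,parenteral,TRUE,2,2,2,3,2,48
Bendamustine powder for infusion,L,parenteral,TRUE,2,3,1,3,2,36
Bromperidol drops for oral use,N,oral,TRUE,2,3,3,2,1,36
Dexamethasone tablet,H,oral,FALSE,2,3,1,3,2,36
Disulfiram dispersible tablet,N,oral,TRUE,2,3,2,3,1,36
Feneticilline capsule,J,oral,TRUE,2,2,1,3,3,36
Flupentixol tablet,N,oral,TRUE,2,3,3,2,1,36
Ibuprofen granules,M,oral,TRUE,2,3,1,2,3,36
Isosorbide mononitrate sustained tablet,C,oral,TRUE,2,3,1,3,2,36
Lamotrigine dispersible tablet,N,oral,FALSE,2,3,2,3,1,36
Olanzapine orodispersible tablet,N,oral,FALSE,2,3,3,2,1,36
Pergolide tablet,N,oral,FALSE,2,3,2,3,1,36
Topiramate tablet,N,oral,FALSE,2,3,2,3,1,36
Vincristine sulfate injection,L,parenteral,FALSE,2,3,1,3,2,36
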