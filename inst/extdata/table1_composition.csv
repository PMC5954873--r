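category,therapy_type,dosage_form,n_products,apis,claims_mg,has_reference,sqtlc_feasible
quinine_sulphate,monotherapy,tablet,6,QUN,300,TRUE,FALSE
quinine_hydrochloride,monotherapy,injection,3,QUN,300,TRUE,TRUE
quinine_bisulphate,monotherapy,mixture,4,QUN,50,TRUE,TRUE
sulphadoxine_pyrimethamine,fixed-dose,tablet,23,SDX;PYR,500;25,TRUE;TRUE,TRUE
artesunate_sp_copack,copacked,tablet,4,ATS;SDX;PYR,100;500;25,TRUE;TRUE;TRUE,TRUE
artemether_lumefantrine,fixed-dose,tablet,41,ATM;LUM,20;120,TRUE;TRUE,TRUE
dha_piperaquine,fixed-dose,tablet,14,DHA;PPQ,40;320,TRUE;FALSE,TRUE
dha_sp,fixed-dose,tablet,12,DHA;SDX;PYR,60;500;25,TRUE;TRUE;TRUE,TRUE
artesunate_smp,fixed-dose,tablet,5,ATS;SM;PYR,100;250;12.5,TRUE;FALSE;TRUE,TRUE
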