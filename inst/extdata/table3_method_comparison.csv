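sample_code,api,group,claim_mg,tlc_pct,tlc_sd,tlc_remark,hplc_pct,hplc_sd,hplc_remark,section
4_2_Y_12,ATS,artesunate_sp_copack,200,91.0,5.5,C,92.77,0.02,C,same
1_12_X_1,LUM,artemether_lumefantrine,480,102.0,4.9,C,102.5,0,C,same
1_13_X_1,LUM,artemether_lumefantrine,480,97.5,5.1,C,109.96,0.0,C,same
2_3_X_1,LUM,artemether_lumefantrine,120,103.0,4.4,C,103.3,0.3,C,same
1_6_Z_1,DHA,dha_piperaquine,40,97.0,7.7,C,97.5,0.9,C,same
1_4_P_10,PYR,sulphadoxine_pyrimethamine,25,98.0,4.6,C,110,0,C,same
4_5_Z_1,PYR,dha_sp,25,103.5,2.4,C,103,0,C,same
4_6_Z_1,PYR,dha_sp,25,99.0,5.1,C,99,0,C,same
1_1_V_5,QUN,quinine,50,107.0,3.7,C,109.7,0.3,C,same
2_3_Z_1,DHA,dha_sp,60,52.5,9.5,NC,54.4,0.2,NC,same
2_4_Z_1,DHA,dha_sp,60,58.0,7.8,NC,52.5,0.1,NC,same
2_4_X_14,LUM,artemether_lumefantrine,120,118.5,3.8,NC,117.5,0.8,NC,same
2X_15,ATM,artemether_lumefantrine,20,135.3,3.7,NC,144.1,0.7,NC,same
1_2_X_14,ATM,artemether_lumefantrine,20,35.0,14.3,NC,35,2,NC,same
4_3_Z_3,DHA,dha_piperaquine,40,75.0,10.0,NC,71,3,NC,same
1_4_Z_3,DHA,dha_piperaquine,40,75.0,6.7,NC,70,1,NC,same
4_1_R_8,QUN,quinine,100,137.5,5.5,NC,291,1,NC,same
1_2_P_2,PYR,sulphadoxine_pyrimethamine,25,74.0,5.4,NC,76,0,NC,same
4V_5,QUN,quinine,50,112.0,4.5,BLC,112,2,BLC,same
1_1_P_2,SDX,sulphadoxine_pyrimethamine,500,86.0,2.3,BLC,87,2,NC,different
1_3_Z_1,SDX,dha_sp,500,88.0,5.1,BLC,86,2,NC,different
3_5_Z_1,SDX,dha_sp,500,88.5,2.8,BLC,84.9,0.1,NC,different
4_4_Y_12,PYR,artesunate_smp,12.5,110.5,4.5,BLC,119,0,NC,different
2_5_X_11,ATM,artemether_lumefantrine,80,111.0,6.8,BLC,113,4,NC,different
4_3_Y_12,PYR,artesunate_smp,12.5,115.0,6.5,BLC,113,0,NC,different
1_7_X_1,ATM,artemether_lumefantrine,80,89.0,5.6,BLC,81.205,0,NC,different
1_9_X_1,LUM,artemether_lumefantrine,480,113.0,4.0,BLC,113.5,0.4,NC,different
3_3_P_10,PYR,sulphadoxine_pyrimethamine,25,88.0,5.1,BLC,87,0,NC,different
2_1_X_1,LUM,artemether_lumefantrine,120,112.0,4.0,BLC,113,4,NC,different
1_2_Z_3,DHA,dha_piperaquine,40,89.0,5.6,BLC,86,2,NC,different
1_2_V_5,QUN,quinine,50,111.0,6.8,BLC,120,1,NC,different
3_2_P_10,PYR,sulphadoxine_pyrimethamine,25,89.5,5.0,BLC,94,0,C,different
2_4_Y_13,ATS,artesunate_sp_copack,100,89.5,5.0,BLC,97.57,0.01,C,different
3_1_X_1,ATM,artemether_lumefantrine,20,89.5,8.4,BLC,92.4,0.6,C,different
1_3_V_5,QUN,quinine,50,109.0,4.6,C,112,1,BLC,different
4_2_Y_12,PYR,artesunate_smp,25,106.0,4.7,C,116,0,NC,different
4_2_Z_3,DHA,dha_piperaquine,40,97.5,5.1,C,87,1,NC,different
3_4_X_1,LUM,artemether_lumefantrine,480,106.0,6.6,C,111.6,0.3,BLC,different
3_2_P_2,PYR,sulphadoxine_pyrimethamine,25,84.5,5.3,NC,96,0,C,different
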