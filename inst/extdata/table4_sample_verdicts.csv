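sample_code,label_claim,tlc_components,tlc_overall,hplc_components,hplc_overall
2_4_Y_13,ATS/SDX/PYR: 100/500/25,BLC|NC|C,NC,C|NC|C,NC
2X_15,ATM/LUM: 20/120,NC|C,NC,NC|C,NC
2_4_X_14,ATM/LUM: 20/120,NC|NC,NC,NC|NC,NC
1_2_X_14,ATM/LUM: 20/120,NC|C,NC,NC|C,NC
2_3_Z_1,DHA/SDX/PYR: 60/500/25,NC|C|C,NC,NC|C|C,NC
2_3_Z_1,DHA/SDX/PYR: 60/500/25,NC|C|C,NC,NC|C|C,NC
1_4_P_10,SDX/PYR: 500/25,NC|C,NC,NC|C,NC
1_3_Z_1,DHA/SDX/PYR: 60/500/25,NC|BLC|C,NC,NC|NC|C,NC
3_5_Z_1,DHA/SDX/PYR: 60/500/25,NC|BLC|C,NC,NC|NC|C,NC
1_6_Z_1,DHA/PPQ: 40/320,C|—,C,C|—,C
1_1_V_5,QUN: 50 mg/5 mL,C,C,C,C
4V_5,QUN: 50 mg/5 mL,BLC,BLC,BLC,BLC
4_2_Y_12,ATS/SM/PYR: 200/500/25,C|—|C,C,C|—|NC,NC
1_9_X_1,ATM/LUM: 80/480,C|BLC,BLC,C|NC,NC
2_1_X_1,ATM/LUM: 20/120,C|BLC,BLC,C|NC,NC
1_1_P_2,SDX/PYR: 500/25,BLC|BLC,BLC,NC|NC,NC
1_2_Z_3,DHA/PPQ: 40/320,BLC|—,BLC,NC|—,NC
1_2_V_5,QUN: 50 mg/5 mL,BLC,BLC,NC,NC
1_3_V_5,QUN: 50 mg/5 mL,C,C,BLC,BLC
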