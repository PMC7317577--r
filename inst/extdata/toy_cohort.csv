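id,visit,visit_time,exposure,L1,L2,followup_time,event,admin_end
1,0,0,3.35758283939045,0.151294338055094,-0.721486916742579,3,0,3
1,1,1,2.76920490851192,0.560889276807056,1.82316429717906,3,0,3
1,2,2,2.9070850529774,0.815835471089524,1.5897608877886,3,0,3
2,0,0,1.77592242864159,0.253829243149435,-0.134443022162674,0.942865916592129,1,3
2,1,1,0,0,0,0.942865916592129,1,3
2,2,2,0,0,0,0.942865916592129,1,3
3,0,0,3.4191365086887,0.000187950046161727,-0.296693838284702,0.117405490456481,1,3
3,1,1,0,0,0,0.117405490456481,1,3
3,2,2,0,0,0,0.117405490456481,1,3
4,0,0,4.03362408274382,0.978986361104329,0.168288440589181,1.94083999498719,1,3
4,1,1,3.54920312918491,0.502281686534377,0.408499969924185,1.94083999498719,1,3
4,2,2,0,0,0,1.94083999498719,1,3
5,0,0,3.31193713979891,0.970895751363407,0.0247048775036445,0.727742583709086,1,3
5,1,1,0,0,0,0.727742583709086,1,3
5,2,2,0,0,0,0.727742583709086,1,3
6,0,0,3.1184186185937,-0.946269511600768,-0.319854882862375,3,0,3
6,1,1,1.74165861181789,-0.780067107338695,-0.0969927887216228,3,0,3
6,2,2,3.18724148252798,0.42172367775541,0.254744853880148,3,0,3
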