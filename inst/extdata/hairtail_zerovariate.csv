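trait,unit,observed,predicted_published,re_published,description
a_b,d,3.29,3.48,0.06,Age of birth
t_p,d,183,205,0.12,Time since birth at puberty
a_m,d,5475,4933,0.10,Life span
L_b,cm,0.5,0.26,0.48,Length at birth
L_p,cm,12,16.5,0.38,Length at puberty
L_i,cm,89.6,68.7,0.23,Ultimate length
W_b,g,4.25e-4,2.87e-4,0.32,Dry weight at birth
W_p,g,80,73.4,0.08,Dry weight at puberty
W_i,g,5000,5267,0.05,Ultimate dry weight
GSI,-,0.04,0.05,0.18,Gonado-somatic index
R_i,1/d,1192,1323,0.11,Maximum reproduction rate
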