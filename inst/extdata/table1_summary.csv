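squid,sex,ml_mm,character,n_analysed,n_available,min_value,max_value,mean,se,s,argmin_subsection,argmax_subsection,range_min_max,range_first_last,gelatinous
F1,female,214,d13c,13,13,-20.5,-18.6,-19.2,0.19,0.78,1,7,1.87,1.82,FALSE
F1,female,214,d15n,13,13,7.9,13.5,11.8,0.54,0.97,2,10,4.60,4.08,FALSE
F1,female,214,tl,13,13,3.0,4.5,4.0,0.14,NA,2,10,1.47,1.07,FALSE
F2,female,215,d13c,13,13,-20.5,-19.4,-19.9,0.09,0.45,3,8,1.04,0.71,FALSE
F2,female,215,d15n,13,13,8.6,13.5,11.4,0.49,0.96,1,8,4.90,3.58,FALSE
F2,female,215,tl,13,13,3.2,4.5,3.9,0.13,NA,1,8,1.29,0.94,FALSE
F3,female,238,d13c,11,15,-20.5,-18.9,-19.6,0.17,0.71,1,14,1.60,1.42,FALSE
F3,female,238,d15n,12,15,10.3,16.7,13.9,0.63,0.97,6,13,6.42,4.30,FALSE
F3,female,238,tl,12,15,3.6,5.3,4.6,0.17,NA,6,13,1.69,1.13,FALSE
F4,female,249,d13c,6,14,-19.4,-18.6,-19.1,0.12,0.40,4,5,0.75,0.06,FALSE
F4,female,249,d15n,10,14,6.4,15.5,11.9,0.82,0.98,2,4,9.09,8.85,FALSE
F4,female,249,tl,10,14,3.0,5.4,4.5,0.22,NA,2,4,2.39,2.33,FALSE
F5,female,257,d13c,9,13,-19.8,-19.0,-19.3,0.09,0.37,4,6,0.76,0.61,FALSE
F5,female,257,d15n,10,13,13.7,16.3,15.6,0.25,0.83,4,11,2.62,1.61,FALSE
F5,female,257,tl,10,13,4.5,5.2,5.0,0.07,NA,4,11,0.69,0.42,FALSE
F6,female,230,d13c,15,15,-20.2,-18.5,-19.2,0.11,0.57,1,15,1.71,1.71,TRUE
F6,female,230,d15n,15,15,11.2,16.7,15.0,0.45,0.96,1,15,5.58,5.58,TRUE
F6,female,230,tl,15,15,3.6,5.1,4.7,0.12,NA,1,15,1.47,1.47,TRUE
M1,male,216,d13c,9,12,-20.1,-18.5,-19.0,0.17,0.66,1,4,1.60,1.05,FALSE
M1,male,216,d15n,9,12,8.9,14.4,12.5,0.65,0.97,1,10,5.41,4.52,FALSE
M1,male,216,tl,9,12,3.3,4.7,4.2,0.17,NA,1,10,1.42,1.19,FALSE
M2,male,221,d13c,11,11,-21.2,-19.3,-19.9,0.20,0.77,1,5,1.90,1.59,FALSE
M2,male,221,d15n,11,11,6.1,12.4,9.9,0.75,0.98,1,10,6.23,5.86,FALSE
M2,male,221,tl,11,11,3.0,4.6,4.0,0.20,NA,1,10,1.64,1.54,FALSE
M3,male,269,d13c,14,14,-21.0,-19.4,-20.0,0.15,0.70,1,8,1.57,1.20,FALSE
M3,male,269,d15n,14,14,9.5,15.4,13.1,0.57,0.97,2,10,5.94,4.29,FALSE
M3,male,269,tl,14,14,3.8,5.3,4.7,0.15,NA,2,10,1.56,1.13,FALSE
M4,male,285,d13c,15,16,-20.3,-18.2,-19.0,0.16,0.74,1,12,2.18,1.02,FALSE
M4,male,285,d15n,15,16,5.6,11.5,9.6,0.53,0.97,1,11,5.97,4.51,FALSE
M4,male,285,tl,15,16,3.0,4.6,4.1,0.14,NA,1,11,1.57,1.19,FALSE
M5,male,252,d13c,14,14,-19.6,-18.9,-19.2,0.05,0.21,3,6,0.72,0.11,FALSE
M5,male,252,d15n,14,14,6.4,12.3,10.3,0.49,0.96,3,10,5.95,1.75,FALSE
M5,male,252,tl,14,14,3.0,4.6,4.1,0.13,NA,3,10,1.56,0.46,FALSE
M6,male,284,d13c,15,15,-20.8,-19.2,-19.7,0.12,0.62,1,14,1.55,1.11,FALSE
M6,male,284,d15n,15,15,11.1,16.6,14.5,0.43,0.96,1,13,5.49,3.18,FALSE
M6,male,284,tl,15,15,3.8,5.3,4.7,0.11,NA,1,13,1.45,0.84,FALSE
M7,male,298,d13c,4,17,-19.5,-19.1,-19.2,0.08,NA,NA,NA,NA,NA,FALSE
M7,male,298,d15n,13,17,10.3,15.4,13.8,0.47,0.96,3,9,5.09,4.27,FALSE
M7,male,298,tl,13,17,4.1,5.4,5.0,0.12,NA,3,9,1.34,1.12,FALSE
M8,male,325,d13c,12,17,-20.7,-19.3,-19.7,0.11,0.51,1,6,1.43,0.80,FALSE
M8,male,325,d15n,14,17,10.7,15.1,13.5,0.42,0.95,2,7,4.41,2.67,FALSE
M8,male,325,tl,14,17,3.7,4.9,4.5,0.11,NA,2,7,1.16,0.70,FALSE
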