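class,label,category,n,mean_length,mean_length_lo,mean_length_hi,mean_width,mean_width_lo,mean_width_hi,var_length,var_length_lo,var_length_hi,var_width,var_width_lo,var_width_hi,r,r_lo,r_hi,ci_suspect
1,Line 1,line,289,9.32,8.20,10.44,NA,NA,NA,19.87,10.08,29.65,NA,NA,NA,NA,NA,NA,FALSE
2,Line 2,line,195,32.36,29.66,35.06,NA,NA,NA,312.35,247.17,337.52,NA,NA,NA,NA,NA,NA,FALSE
3,Film 1,film,714,2.95,2.63,3.26,1.81,1.57,2.05,1.70,1.25,2.15,0.63,0.49,0.76,0.86,0.84,0.88,FALSE
4,Film 2,film,139,9.29,8.50,6.12,5.60,5.08,6.12,14.11,8.68,19.55,7.89,5.25,10.54,0.08,0.05,0.12,TRUE
5,Fragment 1,fragment,4338,2.21,1.93,2.48,1.55,1.36,1.73,0.63,0.32,0.95,0.31,0.15,0.46,0.91,0.88,0.94,FALSE
6,Fragment 2,fragment,1267,5.29,4.69,5.89,3.44,3.15,3.73,5.36,-2.56,13.28,1.35,0.91,1.80,0.15,0.07,0.23,FALSE
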