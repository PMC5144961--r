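trait,quantity,chromosome_type,sex,estimate,se,ci_lo,ci_hi
lifespan,Mean,autosome,F,64.75,0.63,63.45,65.92
lifespan,Mean,autosome,M,50.03,0.69,48.63,51.31
lifespan,Mean,X,F,67.80,0.34,67.13,68.48
lifespan,Mean,X,M,51.36,0.50,50.38,52.33
lifespan,V_L,autosome,F,15.00,3.94,8.85,24.17
lifespan,V_L,autosome,M,17.36,4.56,10.42,27.93
lifespan,V_L,X,F,2.28,1.18,0.28,4.96
lifespan,V_L,X,M,8.95,2.64,5.08,15.38
lifespan,V_V,autosome,F,4.78,0.88,3.24,6.68
lifespan,V_V,autosome,M,4.82,0.91,3.28,6.78
lifespan,V_V,X,F,5.96,1.13,4.14,8.62
lifespan,V_V,X,M,3.19,0.69,2.00,4.68
lifespan,V_R,autosome,F,73.72,1.24,71.38,76.14
lifespan,V_R,autosome,M,89.92,1.43,87.19,92.70
lifespan,V_R,X,F,60.95,1.04,58.92,62.98
lifespan,V_R,X,M,98.84,1.59,95.76,102.02
lifespan,V_P,autosome,F,93.49,4.14,86.74,103.27
lifespan,V_P,autosome,M,112.10,4.75,104.29,122.6
lifespan,V_P,X,F,69.19,1.68,66.03,72.64
lifespan,V_P,X,M,110.98,3.11,105.91,117.96
lifespan,V_A,autosome,F,30.00,7.88,17.70,48.35
lifespan,V_A,autosome,M,34.71,9.12,20.84,55.87
lifespan,V_A,X,F,4.57,2.36,0.57,9.93
lifespan,V_A,X,M,8.95,2.64,5.08,15.38
lifespan,CV_A,autosome,F,0.08,0.01,0.06,0.11
lifespan,CV_A,autosome,M,0.12,0.02,0.09,0.15
lifespan,CV_A,X,F,0.03,0.01,0.01,0.05
lifespan,CV_A,X,M,0.06,0.01,0.04,0.08
aging,Mean,autosome,F,17.29,0.59,16.16,18.44
aging,Mean,autosome,M,12.41,0.34,11.76,13.11
aging,Mean,X,F,14.77,0.34,14.10,15.47
aging,Mean,X,M,10.95,0.20,10.56,11.33
aging,V_L,autosome,F,6.97,4.05,0.43,15.38
aging,V_L,autosome,M,3.07,1.16,1.21,5.72
aging,V_L,X,F,1.01,0.91,0.00,3.28
aging,V_L,X,M,0.78,0.40,0.16,1.72
aging,V_R,autosome,F,25.86,3.93,19.33,34.49
aging,V_R,autosome,M,6.66,0.87,5.16,8.65
aging,V_R,X,F,12.55,1.67,9.60,16.07
aging,V_R,X,M,3.03,0.41,2.32,3.93
aging,V_P,autosome,F,32.83,4.50,25.44,42.28
aging,V_P,autosome,M,9.73,1.27,7.60,12.51
aging,V_P,X,F,13.56,1.70,10.65,17.22
aging,V_P,X,M,3.81,0.48,2.98,4.89
aging,V_A,autosome,F,13.94,8.10,0.86,30.77
aging,V_A,autosome,M,6.14,2.32,2.41,11.43
aging,V_A,X,F,2.02,1.82,0.01,6.56
aging,V_A,X,M,0.78,0.40,0.16,1.72
aging,CV_A,autosome,F,0.206,0.066,0.053,0.326
aging,CV_A,autosome,M,0.196,0.038,0.125,0.274
aging,CV_A,X,F,0.085,0.045,0.006,0.172
aging,CV_A,X,M,0.078,0.021,0.036,0.119
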