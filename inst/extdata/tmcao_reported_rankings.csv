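region,time_point,position,comp_gene,comp_geomean,dct_gene,dct_avg_sd,bk_gene,bk_sd,bk_cv,bk_r,bk_flagged,nf_gene,nf_s,nf_flagged,gn_gene,gn_m
CX,12h,1,Ywhaz,1.00,Ywhaz,0.45,Ywhaz,0.69,2.50,0.967,FALSE,Ywhaz,0.151,FALSE,Ywhaz,0.262
CX,12h,2,Ppia,2.00,Ppia,0.46,Ppia,0.68,2.81,0.961,FALSE,Ppia,0.181,FALSE,Ppia,0.262
CX,12h,3,Hprt1,3.22,Gapdh,0.50,Hprt1,0.80,2.86,0.958,FALSE,Hprt1,0.295,FALSE,Hprt1,0.303
CX,12h,4,Gapdh,3.72,Hprt1,0.51,Gapdh,0.50,2.19,0.921,FALSE,Gapdh,0.300,FALSE,Gapdh,0.341
CX,12h,5,B2m,5.00,B2m,0.66,B2m,0.43,1.81,0.763,TRUE,B2m,0.550,FALSE,B2m,0.440
CX,12h,6,Actb,6.00,Actb,0.82,Actb,1.05,4.41,0.877,FALSE,Actb,0.753,FALSE,Actb,0.567
CX,24h,1,Ppia,1.32,Ppia,0.55,Ywhaz,0.54,1.98,0.894,FALSE,Ppia,0.224,FALSE,Ppia,0.252
CX,24h,2,Hprt1,2.38,Hprt1,0.57,Gapdh,0.58,2.50,0.830,FALSE,Hprt1,0.284,FALSE,Hprt1,0.252
CX,24h,3,Ywhaz,2.45,Ywhaz,0.64,Ppia,0.33,1.47,0.728,FALSE,Ywhaz,0.432,FALSE,Gapdh,0.433
CX,24h,4,Gapdh,3.50,Actb,0.69,Hprt1,0.32,1.23,0.650,FALSE,Actb,0.501,FALSE,Ywhaz,0.497
CX,24h,5,Actb,4.47,Gapdh,0.71,Actb,0.40,1.69,0.456,FALSE,Gapdh,0.586,FALSE,Actb,0.583
CX,24h,6,B2m,6.00,B2m,0.83,B2m,0.42,1.88,0.001,FALSE,B2m,0.738,FALSE,B2m,0.666
CX,3d,1,Ppia,1.32,Ppia,0.65,Ppia,0.98,4.46,0.974,FALSE,Ppia,0.109,FALSE,Ywhaz,0.372
CX,3d,2,Ywhaz,1.68,Ywhaz,0.69,Ywhaz,0.92,3.62,0.934,FALSE,Ywhaz,0.367,FALSE,Hprt1,0.372
CX,3d,3,Hprt1,2.71,Hprt1,0.70,Hprt1,0.81,3.16,0.925,FALSE,Hprt1,0.391,FALSE,Ppia,0.434
CX,3d,4,Gapdh,4.47,Actb,0.80,Gapdh,0.63,2.90,0.745,FALSE,Actb,0.541,FALSE,Gapdh,0.584
CX,3d,5,Actb,4.68,Gapdh,0.95,Actb,1.13,5.20,0.939,TRUE,Gapdh,0.841,TRUE,Actb,0.691
CX,3d,6,B2m,6.00,B2m,1.03,B2m,1.46,6.70,0.931,TRUE,B2m,0.945,TRUE,B2m,0.804
CX,7d,1,Hprt1,1.00,Hprt1,0.65,Hprt1,0.37,1.54,0.873,FALSE,Hprt1,0.221,FALSE,Hprt1,0.477
CX,7d,2,Ppia,2.63,Ppia,0.76,Actb,0.66,3.28,0.851,FALSE,Ppia,0.365,FALSE,Ywhaz,0.477
CX,7d,3,Actb,3.08,Actb,0.81,Ppia,0.42,2.06,0.714,FALSE,Actb,0.463,FALSE,Gapdh,0.509
CX,7d,4,Ywhaz,3.36,Ywhaz,0.81,Ywhaz,0.49,2.09,0.496,FALSE,Ywhaz,0.603,FALSE,Ppia,0.599
CX,7d,5,Gapdh,4.40,Gapdh,0.85,Gapdh,0.47,2.25,0.338,FALSE,Gapdh,0.665,FALSE,Actb,0.656
CX,7d,6,B2m,6.00,B2m,1.25,B2m,1.22,6.04,0.838,TRUE,B2m,1.179,FALSE,B2m,0.855
HIP,12h,1,Ppia,1.19,Ppia,0.25,Actb,0.28,1.42,0.933,FALSE,Ppia,0.076,FALSE,Ppia,0.144
HIP,12h,2,Gapdh,2.21,Gapdh,0.26,Ppia,0.18,0.90,0.872,FALSE,Gapdh,0.107,FALSE,Gapdh,0.144
HIP,12h,3,Actb,2.28,Actb,0.27,Gapdh,0.20,1.02,0.856,FALSE,Actb,0.156,FALSE,Actb,0.182
HIP,12h,4,Hprt1,4.23,Hprt1,0.31,Ywhaz,0.26,1.26,0.671,FALSE,Hprt1,0.213,FALSE,Hprt1,0.221
HIP,12h,5,Ywhaz,4.73,Ywhaz,0.35,Hprt1,0.17,0.78,0.495,FALSE,Ywhaz,0.292,FALSE,Ywhaz,0.254
HIP,12h,6,B2m,6.00,B2m,0.43,B2m,0.26,1.25,0.138,FALSE,B2m,0.394,FALSE,B2m,0.313
HIP,24h,1,Ppia,1.68,B2m,0.29,Ywhaz,0.35,1.71,0.896,FALSE,B2m,0.144,FALSE,Ppia,0.168
HIP,24h,2,B2m,1.73,Ppia,0.30,Ppia,0.33,1.62,0.884,FALSE,Ppia,0.177,FALSE,Ywhaz,0.168
HIP,24h,3,Ywhaz,2.06,Ywhaz,0.31,B2m,0.26,1.25,0.857,FALSE,Ywhaz,0.194,FALSE,B2m,0.254
HIP,24h,4,Actb,4.23,Actb,0.32,Gapdh,0.39,1.99,0.848,FALSE,Actb,0.215,FALSE,Actb,0.268
HIP,24h,5,Gapdh,4.73,Gapdh,0.36,Actb,0.34,1.67,0.844,FALSE,Gapdh,0.301,FALSE,Gapdh,0.289
HIP,24h,6,Hprt1,6.00,Hprt1,0.42,Hprt1,0.22,0.96,0.385,FALSE,Hprt1,0.368,FALSE,Hprt1,0.332
HIP,3d,1,Gapdh,1.00,Gapdh,0.37,Gapdh,0.28,1.44,0.960,FALSE,Gapdh,0.139,FALSE,Gapdh,0.279
HIP,3d,2,Ywhaz,2.91,Ywhaz,0.45,Hprt1,0.65,2.80,0.896,FALSE,Ppia,0.274,FALSE,Ppia,0.279
HIP,3d,3,Ppia,2.99,Actb,0.45,Ywhaz,0.45,2.15,0.893,FALSE,Actb,0.277,FALSE,Ywhaz,0.325
HIP,3d,4,Actb,3.46,Ppia,0.46,Actb,0.47,2.24,0.890,FALSE,Ywhaz,0.278,FALSE,Actb,0.370
HIP,3d,5,Hprt1,3.97,Hprt1,0.54,Ppia,0.36,1.73,0.778,FALSE,Hprt1,0.464,FALSE,Hprt1,0.405
HIP,3d,6,B2m,6.00,B2m,0.66,B2m,0.32,1.48,0.131,FALSE,B2m,0.603,FALSE,B2m,0.489
HIP,7d,1,Ywhaz,1.00,Ywhaz,0.66,Ywhaz,0.51,2.26,0.946,FALSE,Ywhaz,0.146,FALSE,Ywhaz,0.293
HIP,7d,2,Hprt1,2.00,Hprt1,0.69,Hprt1,0.63,2.55,0.914,FALSE,Hprt1,0.207,FALSE,Hprt1,0.293
HIP,7d,3,Actb,3.00,Actb,0.84,Actb,0.82,3.58,0.826,FALSE,Actb,0.557,FALSE,Actb,0.459
HIP,7d,4,B2m,4.00,B2m,0.85,B2m,0.78,3.44,0.825,FALSE,B2m,0.572,FALSE,B2m,0.572
HIP,7d,5,Ppia,5.23,Ppia,1.10,Gapdh,0.68,3.17,0.501,FALSE,Ppia,0.954,FALSE,Ppia,0.746
HIP,7d,6,Gapdh,5.73,Gapdh,1.16,Ppia,0.68,3.00,0.364,FALSE,Gapdh,1.038,FALSE,Gapdh,0.883
DS,12h,1,Hprt1,1.32,Hprt1,0.81,Hprt1,0.28,1.10,0.809,FALSE,Hprt1,0.206,FALSE,Ppia,0.406
DS,12h,2,Ppia,1.68,Ppia,0.90,Ppia,0.58,2.56,0.722,FALSE,Ppia,0.377,FALSE,Ywhaz,0.406
DS,12h,3,Ywhaz,2.91,Ywhaz,0.90,Actb,0.80,3.72,0.511,FALSE,Ywhaz,0.450,FALSE,Hprt1,0.460
DS,12h,4,Gapdh,4.23,Gapdh,1.00,Ywhaz,0.52,2.28,0.553,FALSE,Gapdh,0.623,FALSE,Gapdh,0.550
DS,12h,5,Actb,4.40,Actb,1.27,Gapdh,0.33,1.59,0.129,FALSE,Actb,1.064,FALSE,Actb,0.792
DS,12h,6,B2m,4.73,B2m,1.71,B2m,1.43,6.25,0.823,TRUE,B2m,1.602,FALSE,B2m,1.097
DS,24h,1,Ppia,1.00,Ppia,0.91,Ppia,0.70,3.17,0.938,FALSE,Ppia,0.201,FALSE,Ppia,0.402
DS,24h,2,Hprt1,2.21,Hprt1,1.00,Ywhaz,0.91,4.05,0.851,FALSE,Hprt1,0.464,FALSE,Hprt1,0.402
DS,24h,3,Ywhaz,2.71,Ywhaz,1.04,Hprt1,0.56,2.23,0.832,FALSE,Ywhaz,0.525,FALSE,Ywhaz,0.632
DS,24h,4,B2m,4.42,B2m,1.25,Actb,0.61,2.99,0.209,FALSE,B2m,0.929,FALSE,B2m,0.865
DS,24h,5,Gapdh,5.00,Gapdh,1.46,Gapdh,1.86,8.53,0.969,TRUE,Gapdh,1.273,FALSE,Gapdh,1.040
DS,24h,6,Actb,5.42,Actb,1.52,B2m,1.20,5.34,0.867,TRUE,Actb,1.369,FALSE,Actb,1.199
DS,3d,1,Gapdh,1.32,Gapdh,0.72,Gapdh,0.68,3.41,0.897,FALSE,Gapdh,0.389,FALSE,Ywhaz,0.286
DS,3d,2,Hprt1,2.00,Hprt1,0.73,Hprt1,0.92,3.76,0.897,FALSE,Hprt1,0.483,FALSE,Hprt1,0.286
DS,3d,3,Ywhaz,2.28,Ywhaz,0.74,Ywhaz,0.74,3.40,0.841,FALSE,Ywhaz,0.522,FALSE,Gapdh,0.415
DS,3d,4,B2m,4.23,B2m,0.78,Ppia,0.49,2.41,0.836,FALSE,B2m,0.529,FALSE,B2m,0.626
DS,3d,5,Actb,5.23,Actb,0.89,B2m,1.06,5.27,0.937,TRUE,Actb,0.723,FALSE,Actb,0.716
DS,3d,6,Ppia,5.42,Ppia,0.99,Actb,1.18,6.22,0.923,TRUE,Ppia,0.834,FALSE,Ppia,0.809
DS,7d,1,Ppia,1.00,Ppia,0.77,Ppia,0.25,1.22,0.867,FALSE,Ppia,0.170,FALSE,Ppia,0.314
DS,7d,2,Hprt1,2.00,Hprt1,0.79,Hprt1,0.35,1.44,0.736,FALSE,Hprt1,0.278,FALSE,Hprt1,0.314
DS,7d,3,Ywhaz,3.00,Ywhaz,0.89,Ywhaz,0.34,1.56,0.184,FALSE,Ywhaz,0.709,FALSE,Ywhaz,0.364
DS,7d,4,Gapdh,4.00,Gapdh,0.93,Gapdh,0.27,1.33,0.043,FALSE,Gapdh,0.739,FALSE,Gapdh,0.404
DS,7d,5,Actb,5.23,Actb,1.12,B2m,1.74,9.04,0.955,TRUE,Actb,0.761,FALSE,Actb,0.725
DS,7d,6,B2m,5.73,B2m,1.61,Actb,1.17,6.27,0.952,TRUE,B2m,1.564,FALSE,B2m,1.020
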