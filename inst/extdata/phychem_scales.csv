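residue,hydropathy_kyte_doolittle,hydrophilicity_hopp_woods,hydrophobicity_eisenberg,bulkiness_zimmerman,polarity_grantham,polarity_zimmerman,refractivity,n_codons,pct_buried,pct_accessible,flexibility_bhaskaran,alpha_helix_chou_fasman,beta_sheet_chou_fasman,beta_turn_chou_fasman,coil_deleage_roux,recognition_factors,relative_mutability,molecular_weight,pk_side_chain,net_charge,isoelectric_point
A,1.8,-0.5,0.62,11.50,8.1,0.00,4.34,4,11.2,6.6,0.360,1.42,0.83,0.66,0.824,78,100,89.09,0,0,6.00
C,2.5,-1.0,0.29,13.46,5.5,1.48,35.77,2,4.1,0.9,0.350,0.70,1.19,1.19,0.953,89,20,121.16,8.18,0,5.07
D,-3.5,3.0,-0.90,11.68,13.0,49.70,12.00,2,2.9,7.7,0.510,1.01,0.54,1.46,1.197,81,106,133.10,3.65,-1,2.77
E,-3.5,3.0,-0.74,13.57,12.3,49.90,17.26,2,1.8,5.7,0.500,1.51,0.37,0.74,0.761,78,102,147.13,4.25,-1,3.22
F,2.8,-2.5,1.19,19.80,5.2,0.35,29.40,2,5.1,2.4,0.310,1.13,1.38,0.60,0.797,81,41,165.19,0,0,5.48
G,-0.4,0.0,0.48,3.40,9.0,0.00,0.00,4,11.8,6.7,0.540,0.57,0.75,1.56,1.251,84,49,75.07,0,0,5.97
H,-3.2,-0.5,-0.40,13.69,10.4,51.60,21.81,2,2.0,2.5,0.320,1.00,0.87,0.95,1.068,84,66,155.16,6.00,0.1,7.59
I,4.5,-1.8,1.38,21.40,5.2,0.13,19.06,3,8.6,2.8,0.460,1.08,1.60,0.47,0.886,88,96,131.17,0,0,6.02
K,-3.9,3.0,-1.50,15.71,11.3,49.50,21.29,2,0.5,10.3,0.470,1.16,0.74,1.01,0.897,87,56,146.19,10.53,1,9.74
L,3.8,-1.8,1.06,21.40,4.9,0.13,18.78,6,11.7,4.8,0.370,1.21,1.30,0.59,0.884,85,40,131.17,0,0,5.98
M,1.9,-1.3,0.64,16.25,5.7,1.43,21.64,1,1.9,1.0,0.300,1.45,1.05,0.60,0.810,80,94,149.21,0,0,5.74
N,-3.5,0.2,-0.78,12.82,11.6,3.38,13.28,2,2.9,6.7,0.460,0.67,0.89,1.56,1.167,94,134,132.12,0,0,5.41
P,-1.6,0.0,0.12,17.43,8.0,1.58,10.93,4,2.7,4.8,0.510,0.57,0.55,1.52,1.540,91,56,115.13,0,0,6.30
Q,-3.5,0.2,-0.85,14.45,10.5,3.53,17.56,2,1.6,5.2,0.490,1.11,1.10,0.98,0.947,87,93,146.15,0,0,5.65
R,-4.5,3.0,-2.53,14.28,10.5,52.00,26.66,6,0.5,4.5,0.530,0.98,0.93,0.95,0.893,95,65,174.20,12.48,1,10.76
S,-0.8,0.3,-0.18,9.47,9.2,1.67,6.35,6,8.0,9.4,0.510,0.77,0.75,1.43,1.130,107,120,105.09,0,0,5.68
T,-0.7,-0.4,-0.05,15.77,8.6,1.66,11.01,4,4.9,7.0,0.440,0.83,1.19,0.96,1.148,93,97,119.12,0,0,5.60
V,4.2,-1.5,1.08,21.57,5.9,0.13,13.92,4,12.9,4.5,0.390,1.06,1.70,0.50,0.772,89,74,117.15,0,0,5.96
W,-0.9,-3.4,0.81,21.67,5.4,2.10,42.53,1,2.2,1.4,0.310,1.08,1.37,0.96,0.941,104,18,204.23,0,0,5.89
Y,-1.3,-2.3,0.26,18.03,6.2,1.61,31.53,2,2.6,5.1,0.420,0.69,1.47,1.14,1.109,84,41,181.19,10.07,0,5.66
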