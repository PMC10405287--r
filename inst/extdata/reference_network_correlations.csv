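"network_a","network_b","r","ci_low","ci_high"
"G34_t2","G34_t1",0.4,0.03,0.67
"G34_t3","G34_t1",0.36,-0.02,0.64
"G34_t3","G34_t2",0.32,-0.06,0.62
"G34_t4","G34_t1",0.41,0.05,0.68
"G34_t4","G34_t2",0.32,-0.06,0.62
"G34_t4","G34_t3",0.45,0.09,0.7
"G56_t1","G34_t1",0.48,0.13,0.72
"G56_t1","G34_t2",0.56,0.23,0.77
"G56_t1","G34_t3",0.54,0.2,0.76
"G56_t1","G34_t4",0.43,0.07,0.69
"G56_t2","G34_t1",0.37,0,0.65
"G56_t2","G34_t2",0.34,-0.04,0.63
"G56_t2","G34_t3",0.41,0.04,0.68
"G56_t2","G34_t4",0.51,0.17,0.74
"G56_t2","G56_t1",0.39,0.01,0.66
"G56_t3","G34_t1",0.43,0.07,0.69
"G56_t3","G34_t2",0.48,0.13,0.72
"G56_t3","G34_t3",0.47,0.12,0.72
"G56_t3","G34_t4",0.43,0.07,0.69
"G56_t3","G56_t1",0.75,0.52,0.88
"G56_t3","G56_t2",0.67,0.4,0.84
"G56_t4","G34_t1",0.36,-0.01,0.65
"G56_t4","G34_t2",0.51,0.18,0.74
"G56_t4","G34_t3",0.64,0.34,0.82
"G56_t4","G34_t4",0.55,0.22,0.76
"G56_t4","G56_t1",0.62,0.32,0.81
"G56_t4","G56_t2",0.58,0.27,0.79
"G56_t4","G56_t3",0.63,0.33,0.81
"G78_t1","G34_t1",0.36,-0.02,0.65
"G78_t1","G34_t2",0.55,0.23,0.77
"G78_t1","G34_t3",0.42,0.05,0.68
"G78_t1","G34_t4",0.43,0.07,0.69
"G78_t1","G56_t1",0.57,0.25,0.78
"G78_t1","G56_t2",0.41,0.04,0.68
"G78_t1","G56_t3",0.6,0.3,0.8
"G78_t1","G56_t4",0.52,0.18,0.75
"G78_t2","G34_t1",0.34,-0.04,0.63
"G78_t2","G34_t2",0.54,0.21,0.76
"G78_t2","G34_t3",0.5,0.16,0.74
"G78_t2","G34_t4",0.42,0.05,0.68
"G78_t2","G56_t1",0.71,0.46,0.86
"G78_t2","G56_t2",0.6,0.29,0.79
"G78_t2","G56_t3",0.72,0.47,0.86
"G78_t2","G56_t4",0.69,0.42,0.84
"G78_t2","G78_t1",0.66,0.38,0.83
"G78_t3","G34_t1",0.54,0.21,0.76
"G78_t3","G34_t2",0.62,0.33,0.81
"G78_t3","G34_t3",0.39,0.02,0.67
"G78_t3","G34_t4",0.47,0.12,0.72
"G78_t3","G56_t1",0.72,0.47,0.86
"G78_t3","G56_t2",0.65,0.37,0.82
"G78_t3","G56_t3",0.78,0.58,0.9
"G78_t3","G56_t4",0.69,0.42,0.84
"G78_t3","G78_t1",0.61,0.31,0.8
"G78_t3","G78_t2",0.85,0.69,0.93
"G78_t4","G34_t1",0.55,0.22,0.77
"G78_t4","G34_t2",0.63,0.34,0.81
"G78_t4","G34_t3",0.36,-0.02,0.65
"G78_t4","G34_t4",0.51,0.17,0.74
"G78_t4","G56_t1",0.55,0.22,0.76
"G78_t4","G56_t2",0.63,0.33,0.81
"G78_t4","G56_t3",0.54,0.21,0.76
"G78_t4","G56_t4",0.62,0.33,0.81
"G78_t4","G78_t1",0.61,0.3,0.8
"G78_t4","G78_t2",0.64,0.35,0.82
"G78_t4","G78_t3",0.64,0.35,0.82
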