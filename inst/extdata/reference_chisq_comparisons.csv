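"cohort","timepoint","n","comparison","delta_chisq","delta_df","p_printed"
"G34",1,210,"F1_vs_F2_IR_CM",10.602,1,"0.001"
"G34",1,210,"F1_vs_F2_WM_CM",0.157,1,"0.692"
"G34",1,210,"F1_vs_F2_WM_IR",0.225,1,"0.635"
"G34",1,210,"F2_IR_CM_vs_F3",0.277,2,"0.871"
"G34",1,210,"F2_WM_CM_vs_F3",10.642,2,"0.005"
"G34",1,210,"F2_WM_IR_vs_F3",11.199,2,"0.004"
"G34",2,209,"F1_vs_F2_IR_CM",4.539,1,"0.033"
"G34",2,209,"F1_vs_F2_WM_CM",28.671,1,"<0.001"
"G34",2,209,"F1_vs_F2_WM_IR",20.036,1,"<0.001"
"G34",2,209,"F2_IR_CM_vs_F3",21.504,2,"<0.001"
"G34",2,209,"F2_WM_CM_vs_F3",3.486,2,"0.175"
"G34",2,209,"F2_WM_IR_vs_F3",12.052,2,"0.002"
"G34",3,217,"F1_vs_F2_IR_CM",0.002,1,"0.962"
"G34",3,217,"F1_vs_F2_WM_CM",2.975,1,"0.085"
"G34",3,217,"F1_vs_F2_WM_IR",1.449,1,"0.229"
"G34",3,217,"F2_IR_CM_vs_F3",3.662,2,"0.160"
"G34",3,217,"F2_WM_CM_vs_F3",0.255,2,"0.880"
"G34",3,217,"F2_WM_IR_vs_F3",2.155,2,"0.340"
"G34",4,234,"F1_vs_F2_IR_CM",2.804,1,"0.094"
"G34",4,234,"F1_vs_F2_WM_CM",3.513,1,"0.061"
"G34",4,234,"F1_vs_F2_WM_IR",11.037,1,"0.001"
"G34",4,234,"F2_IR_CM_vs_F3",10.544,2,"0.005"
"G34",4,234,"F2_WM_CM_vs_F3",10.116,2,"0.006"
"G34",4,234,"F2_WM_IR_vs_F3",2.397,2,"0.302"
"G56",1,211,"F1_vs_F2_IR_CM",9.077,1,"0.003"
"G56",1,211,"F1_vs_F2_WM_CM",1.5,1,"0.221"
"G56",1,211,"F1_vs_F2_WM_IR",3.059,1,"0.080"
"G56",1,211,"F2_IR_CM_vs_F3",3.056,2,"0.217"
"G56",1,211,"F2_WM_CM_vs_F3",10.232,2,"0.006"
"G56",1,211,"F2_WM_IR_vs_F3",9.389,2,"0.009"
"G56",2,201,"F1_vs_F2_IR_CM",9.685,1,"0.002"
"G56",2,201,"F1_vs_F2_WM_CM",18.086,1,"<0.001"
"G56",2,201,"F1_vs_F2_WM_IR",9.551,1,"0.002"
"G56",2,201,"F2_IR_CM_vs_F3",12.839,2,"0.002"
"G56",2,201,"F2_WM_CM_vs_F3",7.828,2,"0.020"
"G56",2,201,"F2_WM_IR_vs_F3",14.254,2,"0.001"
"G56",3,281,"F1_vs_F2_IR_CM",10.905,1,"0.001"
"G56",3,281,"F1_vs_F2_WM_CM",2.194,1,"0.139"
"G56",3,281,"F1_vs_F2_WM_IR",17.954,1,"<0.001"
"G56",3,281,"F2_IR_CM_vs_F3",15.696,2,"<0.001"
"G56",3,281,"F2_WM_CM_vs_F3",30.375,2,"<0.001"
"G56",3,281,"F2_WM_IR_vs_F3",10.741,2,"0.005"
"G56",4,273,"F1_vs_F2_IR_CM",9.23,1,"0.002"
"G56",4,273,"F1_vs_F2_WM_CM",14.339,1,"<0.001"
"G56",4,273,"F1_vs_F2_WM_IR",38.936,1,"<0.001"
"G56",4,273,"F2_IR_CM_vs_F3",18.365,2,"<0.001"
"G56",4,273,"F2_WM_CM_vs_F3",13.323,2,"0.001"
"G56",4,273,"F2_WM_IR_vs_F3",7.003,2,"0.030"
"G78",1,447,"F1_vs_F2_IR_CM",10.761,1,"0.001"
"G78",1,447,"F1_vs_F2_WM_CM",2.335,1,"0.126"
"G78",1,447,"F1_vs_F2_WM_IR",5.982,1,"0.014"
"G78",1,447,"F2_IR_CM_vs_F3",5.445,2,"0.066"
"G78",1,447,"F2_WM_CM_vs_F3",14.184,2,"0.001"
"G78",1,447,"F2_WM_IR_vs_F3",10.575,2,"0.005"
"G78",2,453,"F1_vs_F2_IR_CM",13.883,1,"<0.001"
"G78",2,453,"F1_vs_F2_WM_CM",5.112,1,"0.024"
"G78",2,453,"F1_vs_F2_WM_IR",6.9,1,"0.009"
"G78",2,453,"F2_IR_CM_vs_F3",6.739,2,"0.034"
"G78",2,453,"F2_WM_CM_vs_F3",15.111,2,"0.001"
"G78",2,453,"F2_WM_IR_vs_F3",13.203,2,"0.001"
"G78",3,432,"F1_vs_F2_IR_CM",26.161,1,"<0.001"
"G78",3,432,"F1_vs_F2_WM_CM",7.093,1,"0.008"
"G78",3,432,"F1_vs_F2_WM_IR",21.051,1,"<0.001"
"G78",3,432,"F2_IR_CM_vs_F3",18.276,2,"<0.001"
"G78",3,432,"F2_WM_CM_vs_F3",38.066,2,"<0.001"
"G78",3,432,"F2_WM_IR_vs_F3",20.456,2,"<0.001"
"G78",4,410,"F1_vs_F2_IR_CM",42.235,1,"<0.001"
"G78",4,410,"F1_vs_F2_WM_CM",20.249,1,"<0.001"
"G78",4,410,"F1_vs_F2_WM_IR",37.355,1,"<0.001"
"G78",4,410,"F2_IR_CM_vs_F3",33.262,2,"<0.001"
"G78",4,410,"F2_WM_CM_vs_F3",57.776,2,"<0.001"
"G78",4,410,"F2_WM_IR_vs_F3",41.058,2,"<0.001"
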