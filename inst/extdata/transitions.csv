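from_state,to_state,annual_prob,dist_family,dist_a,dist_b,derivation_flag
Healthy,Obesity,0.0246,beta,50,950,literature
Healthy,PreDM,0.0224,beta,20,980,literature
Healthy,PreHTN,0.0037,beta,30,970,literature
Obesity,PreDM,0.0381,beta,80,920,literature
Obesity,DM,0.0164,beta,30,970,literature
PreDM,DM,0.0112,beta,70,930,literature
PreDM,HighRiskDM,0.0044,beta,10,990,derived
PreHTN,HTN,0.0041,beta,50,950,literature
HTN,HTN2,0.0025,beta,20,980,derived
DM,HighRiskDM,0.0131,beta,30,970,literature
DM_HTN,HighRiskDM,0.0157,beta,40,960,derived
OB_HTN,OB_HTN_DM,0.0004,beta,0.4,999.6,calibrated
OB_DM,OB_HTN_DM,0.0004,beta,0.4,999.6,calibrated
OB_DM,HighRiskDM,0.0004,beta,0.4,999.6,calibrated
OB_HTN_DM,HighRiskDM,0.0004,beta,0.4,999.6,calibrated
ANY,CAD,0.0016,beta,10,990,literature
ANY,MI,0.001,beta,50,950,literature
ANY,CHF,0.0026,beta,20,980,literature
ANY,Stroke,0.002,beta,10,990,literature
ANY,DEATH,NA,beta,NA,NA,age_specific
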