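state_id,label,annual_cost_usd,utility,cost_dist_family,cost_a,cost_b,utility_dist_family,utility_a,utility_b,reversible
Healthy,Healthy,0,1,gamma,100,0,beta,17.1,0.9,FALSE
Obesity,Obesity,1200,0.88,gamma,100,12,beta,880,120,TRUE
PreDM,Pre-Diabetes,3000,0.87,gamma,100,30,beta,87,13,FALSE
PreHTN,Pre-Hypertension,1000,0.86,gamma,100,10,beta,86,14,FALSE
HTN,Hypertension (HTN),2500,0.85,gamma,100,25,beta,850,150,TRUE
HTN2,HTN Stage 2,4000,0.8,gamma,100,40,beta,80,20,FALSE
DM,Diabetes (DM),9500,0.7,gamma,100,95,beta,70,30,TRUE
CAD,Ischemic Heart Disease (CAD),12000,0.78,gamma,100,120,beta,780,220,FALSE
MI,Myocardial Infarction (MI),20000,0.75,gamma,100,200,beta,75,25,FALSE
CHF,Congestive Heart Failure (CHF),14000,0.68,gamma,100,140,beta,68,32,FALSE
Stroke,Stroke,12000,0.6,gamma,100,120,beta,60,40,FALSE
DM_HTN,DM + HTN,11000,0.6,gamma,100,110,beta,60,40,FALSE
OB_HTN,Obesity + HTN,3200,0.75,gamma,100,32,beta,75,25,FALSE
OB_DM,Obesity + DM,10700,0.62,gamma,100,107,beta,62,38,FALSE
OB_HTN_DM,Obesity + HTN + DM,12500,0.55,gamma,100,125,beta,55,45,FALSE
HighRiskDM,High-Risk Diabetes,14500,0.55,gamma,100,145,beta,55,45,FALSE
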