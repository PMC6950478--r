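outcome,category,beta,beta_low,beta_high,incidence,work_loss_days
all_cause_mortality,mortality,0.00296,0.00076,0.00504,NA,250
respiratory_admission,inpatient,0.00109,0.00000,0.00221,0.01619,1.75
cardiovascular_admission,inpatient,0.00068,0.00043,0.00093,0.00855,25.8
pediatric_outpatient,outpatient,0.00056,0.00020,0.00090,0.22043,0.5
internal_medicine_outpatient,outpatient,0.00049,0.00027,0.00070,0.66551,0.91
chronic_bronchitis,unattended,0.01009,0.00366,0.01559,0.00694,1.38
acute_bronchitis,unattended,0.00790,0.00270,0.01300,0.03800,0.55
asthma,unattended,0.00210,0.00145,0.00274,0.01190,0.55
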