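"label","cost_gbp","category","source","staff_gbp","n_appointments","n_full_tests","n_predictive_tests"
"oncology_referral","168.00","referral","NHS reference costs 2012-13 (oncology clinic appointment)","0","0","0","0"
"gp_referral","43.00","referral","calibrated","0","0","0","0"
"referral_received","5.07","administration","primary data collection","5.07","0","0","0"
"referral_triaged","1.17","administration","primary data collection","1.17","0","0","0"
"request_documents","8.82","administration","primary data collection","8.82","0","0","0"
"clinical_review","21.85","administration","primary data collection","21.85","0","0","0"
"appointment_arranged","3.49","administration","primary data collection","3.49","0","0","0"
"clinic_preparation","2.74","administration","primary data collection","2.74","0","0","0"
"clinic_appointment","104.80","clinic","primary data collection","104.80","1","0","0"
"post_appointment_letter","11.18","clinic","primary data collection","11.18","0","0","0"
"post_appointment_admin","5.17","clinic","primary data collection","5.17","0","0","0"
"phlebotomy","3.00","sample","primary data collection","0","0","0","0"
"brca_full_test","540.00","test","TGLclinical 2013 (Sanger + MLPA)","0","0","1","0"
"brca_predictive_test","107.99","test","calibrated","0","0","0","1"
"mammography","45.50","management","Taylor-Phillips et al.","0","0","0","0"
"mri","145.88","management","NHS reference costs","0","0","0","0"
"mastectomy","6784.00","management","NHS reference costs; NICE","0","0","0","0"
"salpingo_oophorectomy","3355.43","management","NICE; NHS reference costs","0","0","0","0"
"surveillance_population","169.22","management","calibrated","0","0","0","0"
"surveillance_moderate","578.79","management","calibrated","0","0","0","0"
"surveillance_higher","628.30","management","printed aggregate (pathway itemization)","0","0","0","0"
"carrier_management_affected","4603.49","management","calibrated","0","0","0","0"
"carrier_management_unaffected","7498.90","management","calibrated","0","0","0","0"
"relative_carrier_block","5608.54","composite","calibrated","291.67","2","1","0"
"relative_negative_loop","1243.40","composite","calibrated","291.67","2","1","0"
"intervening_relative_block","742.25","composite","calibrated","291.67","2","0","1"
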