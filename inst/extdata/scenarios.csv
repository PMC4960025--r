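"label","test_price","consultant_fraction","face_to_face_fraction","london_weighting"
"Base case",NA,1,1,TRUE
"Removal of London weighting",NA,1,1,FALSE
"Test at £300",300,1,1,TRUE
"Test at £400",400,1,1,TRUE
"Test at £600",600,1,1,TRUE
"Test at £700",700,1,1,TRUE
"Test at £1000",1000,1,1,TRUE
"25% consultant, 75% genetic counsellor appointments",NA,0.25,1,TRUE
"50% consultant, 50% genetic counsellor appointments",NA,0.5,1,TRUE
"75% consultant, 25% genetic counsellor appointments",NA,0.75,1,TRUE
"25% telephone, 75% clinic appointments",NA,1,0.75,TRUE
"50% telephone, 50% clinic appointments",NA,1,0.5,TRUE
"75% telephone, 25% clinic appointments",NA,1,0.25,TRUE
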