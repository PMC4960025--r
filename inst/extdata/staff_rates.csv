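"band_label","hourly_rate_gbp","london_weighted","source"
"band3_administrative_assistant",17.19,TRUE,"NHS Agenda for Change"
"band5_medical_secretary",23.48,TRUE,"NHS Agenda for Change"
"band6_administrative_lead",28.74,TRUE,"NHS Agenda for Change"
"band8_genetic_counsellor",55.54,TRUE,"NHS Agenda for Change"
"registrar",61.46,TRUE,"PSSRU"
"consultant",139.73,TRUE,"PSSRU"
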