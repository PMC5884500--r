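illness,value_1995,value_2010,printed_rate,exact
chronic,5.9,11.6,4.6,TRUE
asthma,5.1,8.3,3.3,TRUE
diabetes,8.3,18.0,5.3,TRUE
heart_conditions,11.2,32.4,7.4,FALSE
epilepsy,7.5,6.6,-0.8,TRUE
occupational_illness,5.0,1.4,-8.1,TRUE
cancer,8.4,16.9,4.8,TRUE
recent_acute,14.3,11.4,-1.5,TRUE
nonspecific_fever,8.2,8.1,NA,NA
diarrhea,9.9,4.5,-5.2,FALSE
respiratory,30.9,15.0,-4.7,TRUE
skin_disease,15.4,4.0,-8.6,TRUE
dysentery,9.4,11.1,1.1,TRUE
malaria,31.8,12.9,-5.9,FALSE
jaundice,20.9,23.5,0.8,TRUE
parasites,10.2,17.7,3.8,FALSE
tuberculosis,60.3,8.8,-12.0,TRUE
injury,12.9,36.9,7.3,TRUE
other,13.3,18.4,2.2,TRUE
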