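illness,value_1995,value_2010,printed_rate,exact
chronic,12.0,9.6,-1.5,TRUE
asthma,8.5,11.5,2.0,TRUE
diabetes,7.4,13.9,4.3,TRUE
heart_conditions,17.2,23.0,2.0,TRUE
epilepsy,16.2,12.1,-1.9,TRUE
cancer,44.5,42.9,-0.3,FALSE
recent_acute,21.1,7.8,-6.4,TRUE
nonspecific_fever,18.9,9.4,-4.6,FALSE
diarrhea,18.9,6.8,-6.6,TRUE
respiratory,39.0,16.2,-5.7,TRUE
skin_disease,33.3,8.3,-8.9,FALSE
dysentery,16.2,7.6,-4.9,TRUE
malaria,20.7,28.1,2.1,TRUE
jaundice,28.8,40.0,2.2,TRUE
parasites,13.3,21.3,3.2,TRUE
measles,20.4,0.7,-20.1,TRUE
tuberculosis,58.9,17.5,-7.8,TRUE
injury,30.7,22.4,-2.1,TRUE
other,20.5,19.8,-0.2,TRUE
total,19.3,10.6,-3.9,TRUE
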