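indicator,era,years,incidence,ci_low,ci_high
catastrophic_total10,recent,2010-2014,0.155,0.123,0.190
catastrophic_total10,early,1992-1996,0.089,0.067,0.115
catastrophic_nonfood40,recent,2011-2014,0.127,0.083,0.179
catastrophic_nonfood40,early,1992-1996,0.040,0.025,0.058
catastrophic_ctp40,recent,2010-2012,0.053,0.035,0.074
catastrophic_ctp40,early,1993-1995,0.038,0.034,0.041
impoverishment,recent,2011-2012,0.036,0.029,0.044
impoverishment,early,1993-1996,0.031,0.024,0.038
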