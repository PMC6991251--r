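outcome,cohort_size,reason,count
mi,127600,admin_end,36187
mi,127600,disenrollment,11442
mi,127600,pregnancy,361
mi,127600,death_censoring,4983
mi,127600,event,1729
mi,127600,interruption,72898
mortality,127600,admin_end,36691
mortality,127600,disenrollment,11429
mortality,127600,pregnancy,362
mortality,127600,event,5464
mortality,127600,interruption,73654
cva,127600,admin_end,36398
cva,127600,disenrollment,11476
cva,127600,pregnancy,361
cva,127600,death_censoring,5043
cva,127600,event,1301
cva,127600,interruption,73021
chf,127600,admin_end,36058
chf,127600,disenrollment,11387
chf,127600,pregnancy,360
chf,127600,death_censoring,4535
chf,127600,event,3082
chf,127600,interruption,72178
cvd_mortality,95300,admin_end,31171
cvd_mortality,95300,disenrollment,7889
cvd_mortality,95300,pregnancy,268
cvd_mortality,95300,death_censoring,2328
cvd_mortality,95300,event,1588
cvd_mortality,95300,interruption,52056
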