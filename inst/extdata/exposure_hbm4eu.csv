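study_id,country,population,biomarker,n,p05,p50,p95,p95_lcl,p95_ucl,note
3xG,Belgium,children,3-PBA,NR,NR,NR,7.05,NR,NR,printed p95
SLO-CRP,Slovenia,children,3-PBA,NR,NR,NR,3.72,NR,NR,printed p95
ORGANIKO,Cyprus,children,3-PBA,NR,NR,NR,6.34,NR,NR,back-calculated from printed screening RCR 1.95 x 3.25
ESTEBAN,France,children,3-PBA,NR,NR,NR,NR,NR,NR,p95 exceeded the screening value per study text but the value is not printed
RAV-MABAT,Israel,children,3-PBA,NR,NR,NR,NR,NR,NR,p95 exceeded the screening value per study text but the value is not printed; upper confidence limit referenced but unprinted
SPECIMEN,Netherlands,children,3-PBA,NR,NR,NR,NR,NR,NR,p95 exceeded the screening value per study text but the value is not printed
RAV-MABAT,Israel,children,ClF3CA,NR,NR,NR,0.765,NR,NR,back-calculated from RCR table (0.085 x 9)
SPECIMEN,Netherlands,children,ClF3CA,NR,NR,NR,1.28,NR,NR,printed p95
3xG,Belgium,children,ClF3CA,NR,NR,NR,0.774,NR,NR,back-calculated from RCR table (0.086 x 9)
ORGANIKO,Cyprus,children,ClF3CA,NR,NR,NR,0.261,NR,NR,back-calculated from RCR table (0.029 x 9)
ESTEBAN,France,children,ClF3CA,NR,NR,NR,NR,NR,NR,not measured
SLO-CRP,Slovenia,children,ClF3CA,NR,NR,NR,NR,NR,NR,below detection frequency threshold
RAV-MABAT,Israel,children,DBCA,NR,NR,NR,0.99,NR,NR,back-calculated from RCR table (0.011 x 90)
SPECIMEN,Netherlands,children,DBCA,NR,NR,NR,3.78,NR,NR,back-calculated from RCR table (0.042 x 90)
3xG,Belgium,children,DBCA,NR,NR,NR,3.06,NR,NR,back-calculated from RCR table (0.034 x 90)
ORGANIKO,Cyprus,children,DBCA,NR,NR,NR,3.96,NR,NR,back-calculated from RCR table (0.044 x 90)
ESTEBAN,France,children,DBCA,NR,NR,NR,5.32,NR,NR,printed p95
SLO-CRP,Slovenia,children,DBCA,NR,NR,NR,NR,NR,NR,below detection frequency threshold
RAV-MABAT,Israel,children,DCCA,NR,NR,NR,5.1,NR,NR,back-calculated from RCR table (0.17 x 30)
SPECIMEN,Netherlands,children,DCCA,NR,NR,NR,4.5,NR,NR,back-calculated from RCR table (0.15 x 30)
3xG,Belgium,children,DCCA,NR,NR,NR,7.52,NR,NR,printed p95; study text also prints 7.5 for the same quantity and 7.52 reproduces the permethrin RCR cell
ORGANIKO,Cyprus,children,DCCA,NR,NR,NR,6.0,NR,NR,back-calculated from RCR table (0.20 x 30)
ESTEBAN,France,children,DCCA,NR,NR,NR,3.24,NR,NR,back-calculated from RCR table (0.108 x 30); study text prints 3.2
SLO-CRP,Slovenia,children,DCCA,NR,NR,NR,NR,NR,NR,below detection frequency threshold
RAV-MABAT,Israel,children,4-FPBA,NR,NR,NR,0.208,NR,NR,back-calculated from RCR table (0.013 x 16.0)
SPECIMEN,Netherlands,children,4-FPBA,NR,NR,NR,NR,NR,NR,below detection frequency threshold
3xG,Belgium,children,4-FPBA,NR,NR,NR,NR,NR,NR,below detection frequency threshold
ORGANIKO,Cyprus,children,4-FPBA,NR,NR,NR,NR,NR,NR,below detection frequency threshold
ESTEBAN,France,children,4-FPBA,NR,NR,NR,0.064,NR,NR,back-calculated from RCR table (0.004 x 16.0)
SLO-CRP,Slovenia,children,4-FPBA,NR,NR,NR,0.29,NR,NR,printed p95
RAV-MABAT,Israel,adults,3-PBA,NR,NR,NR,2.87,NR,NR,printed p95; highest adult value
ESTEBAN,France,adults,3-PBA,NR,NR,NR,NR,NR,NR,below the screening value per study text; value not printed
ESB,Germany,adults,3-PBA,NR,NR,NR,NR,NR,NR,below the screening value per study text; value not printed
HBM4EU-CH,Switzerland,adults,3-PBA,NR,NR,NR,NR,NR,NR,below the screening value per study text; value not printed
RAV-MABAT,Israel,adults,3-PBA+4-FPBA,NR,NR,NR,3.13,NR,NR,printed p95; reported sum of both markers
HBM4EU-CH,Switzerland,adults,ClF3CA,NR,NR,NR,0.434,NR,NR,back-calculated from RCR table (0.031 x 14)
ESB,Germany,adults,ClF3CA,NR,NR,NR,0.266,NR,NR,back-calculated from RCR table (0.019 x 14)
RAV-MABAT,Israel,adults,ClF3CA,NR,NR,NR,1.05,NR,NR,printed p95
ESTEBAN,France,adults,ClF3CA,NR,NR,NR,NR,NR,NR,not measured
HBM4EU-CH,Switzerland,adults,DBCA,NR,NR,NR,0.884,NR,NR,back-calculated from RCR table (0.0068 x 130)
ESB,Germany,adults,DBCA,NR,NR,NR,0.533,NR,NR,back-calculated from RCR table (0.0041 x 130)
RAV-MABAT,Israel,adults,DBCA,NR,NR,NR,0.416,NR,NR,back-calculated from RCR table (0.0032 x 130)
ESTEBAN,France,adults,DBCA,NR,NR,NR,5.37,NR,NR,printed p95; highest adult value
HBM4EU-CH,Switzerland,adults,DCCA,NR,NR,NR,1.62,NR,NR,back-calculated from RCR table (0.036 x 45)
ESB,Germany,adults,DCCA,NR,NR,NR,0.85,NR,NR,printed p95; lowest adult value
RAV-MABAT,Israel,adults,DCCA,NR,NR,NR,3.08,NR,NR,printed p95; highest adult value
ESTEBAN,France,adults,DCCA,NR,NR,NR,2.385,NR,NR,back-calculated from RCR table (0.053 x 45)
ESTEBAN,France,adults,4-FPBA,NR,NR,NR,0.07,NR,NR,printed p95; highest adult value
HBM4EU-CH,Switzerland,adults,4-FPBA,NR,NR,NR,NR,NR,NR,below detection frequency threshold
ESB,Germany,adults,4-FPBA,NR,NR,NR,NR,NR,NR,below detection frequency threshold
RAV-MABAT,Israel,adults,4-FPBA,NR,NR,NR,NR,NR,NR,below detection frequency threshold
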