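phecode,icd,system,exclude_low,exclude_high
274.1,M10,ICD10,274,274.99
274.11,M100,ICD10,274,274.99
401.1,I10,ICD10,401,405.99
411.2,I21,ICD10,410,414.99
411.8,I25,ICD10,410,414.99
411.3,I20,ICD10,410,414.99
428.1,I50,ICD10,425,429.99
433,I63,ICD10,430,438.99
272.11,E78,ICD10,272,272.99
250.2,E11,ICD10,249,250.99
250.1,E10,ICD10,249,250.99
278.1,E66,ICD10,278,278.99
495,J45,ICD10,490,495.99
599,N39,ICD10,599,599.99
274.1,2749,ICD9,274,274.99
401.1,4019,ICD9,401,405.99
495,49390,ICD9,490,495.99
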