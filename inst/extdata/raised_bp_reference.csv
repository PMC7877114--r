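component,threshold,group,n_base,n_follow,N
systolic,135,telemonitoring,190,94,399
systolic,140,telemonitoring,138,51,399
systolic,145,telemonitoring,92,37,399
systolic,150,telemonitoring,62,20,399
diastolic,85,telemonitoring,138,66,399
diastolic,90,telemonitoring,90,23,399
systolic,135,comparator,2119,1879,3484
systolic,140,comparator,1658,1414,3484
systolic,145,comparator,1132,854,3484
systolic,150,comparator,894,555,3484
diastolic,85,comparator,1080,799,3484
diastolic,90,comparator,672,411,3484
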