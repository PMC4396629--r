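type,location,gender,source,median,mad,min,max
simulated,mid-face,female,M1,2.5,0.5,2,5
simulated,mid-face,female,M2,6,0.5,5,7
simulated,mid-face,female,M3,5.5,1,4,8
simulated,mid-face,female,M4,4.5,0.5,3,5
simulated,mid-face,female,M5,6,0.5,4,7
simulated,mid-face,female,M6,5.5,1.5,3,7
simulated,mid-face,male,M1,4,1.5,2,7
simulated,mid-face,male,M2,5,1.5,2,7
simulated,mid-face,male,M3,5,0,3,5
simulated,mid-face,male,M4,4.5,0.5,4,6
simulated,mid-face,male,M5,5.5,2,3,8
simulated,mid-face,male,M6,7,0.5,4,8
simulated,peripheral,female,P1,7.5,0.5,7,9
simulated,peripheral,female,P2,6.5,0.5,6,8
simulated,peripheral,female,P3,6.5,0.5,5,7
simulated,peripheral,female,P4,6,1,2,7
simulated,peripheral,female,P5,6.5,0.5,4,7
simulated,peripheral,female,P6,6,1,5,8
simulated,peripheral,female,P7,7,0.5,6,8
simulated,peripheral,male,P1,7,0,7,9
simulated,peripheral,male,P2,6.5,1,4,8
simulated,peripheral,male,P3,7,0.5,5,8
simulated,peripheral,male,P4,6,1,4,7
simulated,peripheral,male,P5,7,0.5,5,8
simulated,peripheral,male,P6,6.5,1,3,8
simulated,peripheral,male,P7,6,1,6,8
real,mid-face,n/a,R1,8,0.5,7,9
real,peripheral,n/a,R2,6.5,1,5,8
exaggerated,mid-face,n/a,M1,2,0.5,1,4
exaggerated,mid-face,n/a,M3,1.5,0.5,1,3
exaggerated,peripheral,n/a,P2,1,0,1,2
exaggerated,peripheral,n/a,P3,2,0.5,1,7
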