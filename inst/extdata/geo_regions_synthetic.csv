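kind,key,region
ip24,10.1.0,AL
ip24,10.1.1,AL
ip24,10.1.2,AL
ip24,10.1.3,AL
ip24,10.10.0,GA
ip24,10.10.1,GA
ip24,10.10.2,GA
ip24,10.10.3,GA
ip24,10.11.0,HI
ip24,10.11.1,HI
ip24,10.11.2,HI
ip24,10.11.3,HI
ip24,10.12.0,ID
ip24,10.12.1,ID
ip24,10.12.2,ID
ip24,10.12.3,ID
ip24,10.13.0,IL
ip24,10.13.1,IL
ip24,10.13.2,IL
ip24,10.13.3,IL
ip24,10.14.0,IN
ip24,10.14.1,IN
ip24,10.14.2,IN
ip24,10.14.3,IN
ip24,10.15.0,IA
ip24,10.15.1,IA
ip24,10.15.2,IA
ip24,10.15.3,IA
ip24,10.16.0,KS
ip24,10.16.1,KS
ip24,10.16.2,KS
ip24,10.16.3,KS
ip24,10.17.0,KY
ip24,10.17.1,KY
ip24,10.17.2,KY
ip24,10.17.3,KY
ip24,10.18.0,LA
ip24,10.18.1,LA
ip24,10.18.2,LA
ip24,10.18.3,LA
ip24,10.19.0,ME
ip24,10.19.1,ME
ip24,10.19.2,ME
ip24,10.19.3,ME
ip24,10.2.0,AK
ip24,10.2.1,AK
ip24,10.2.2,AK
ip24,10.2.3,AK
ip24,10.20.0,MD
ip24,10.20.1,MD
ip24,10.20.2,MD
ip24,10.20.3,MD
ip24,10.21.0,MA
ip24,10.21.1,MA
ip24,10.21.2,MA
ip24,10.21.3,MA
ip24,10.22.0,MI
ip24,10.22.1,MI
ip24,10.22.2,MI
ip24,10.22.3,MI
ip24,10.23.0,MN
ip24,10.23.1,MN
ip24,10.23.2,MN
ip24,10.23.3,MN
ip24,10.24.0,MS
ip24,10.24.1,MS
ip24,10.24.2,MS
ip24,10.24.3,MS
ip24,10.25.0,MO
ip24,10.25.1,MO
ip24,10.25.2,MO
ip24,10.25.3,MO
ip24,10.26.0,MT
ip24,10.26.1,MT
ip24,10.26.2,MT
ip24,10.26.3,MT
ip24,10.27.0,NE
ip24,10.27.1,NE
ip24,10.27.2,NE
ip24,10.27.3,NE
ip24,10.28.0,NV
ip24,10.28.1,NV
ip24,10.28.2,NV
ip24,10.28.3,NV
ip24,10.29.0,NH
ip24,10.29.1,NH
ip24,10.29.2,NH
ip24,10.29.3,NH
ip24,10.3.0,AZ
ip24,10.3.1,AZ
ip24,10.3.2,AZ
ip24,10.3.3,AZ
ip24,10.30.0,NJ
ip24,10.30.1,NJ
ip24,10.30.2,NJ
ip24,10.30.3,NJ
ip24,10.31.0,NM
ip24,10.31.1,NM
ip24,10.31.2,NM
ip24,10.31.3,NM
ip24,10.32.0,NY
ip24,10.32.1,NY
ip24,10.32.2,NY
ip24,10.32.3,NY
ip24,10.33.0,NC
ip24,10.33.1,NC
ip24,10.33.2,NC
ip24,10.33.3,NC
ip24,10.34.0,ND
ip24,10.34.1,ND
ip24,10.34.2,ND
ip24,10.34.3,ND
ip24,10.35.0,OH
ip24,10.35.1,OH
ip24,10.35.2,OH
ip24,10.35.3,OH
ip24,10.36.0,OK
ip24,10.36.1,OK
ip24,10.36.2,OK
ip24,10.36.3,OK
ip24,10.37.0,OR
ip24,10.37.1,OR
ip24,10.37.2,OR
ip24,10.37.3,OR
ip24,10.38.0,PA
ip24,10.38.1,PA
ip24,10.38.2,PA
ip24,10.38.3,PA
ip24,10.39.0,RI
ip24,10.39.1,RI
ip24,10.39.2,RI
ip24,10.39.3,RI
ip24,10.4.0,AR
ip24,10.4.1,AR
ip24,10.4.2,AR
ip24,10.4.3,AR
ip24,10.40.0,SC
ip24,10.40.1,SC
ip24,10.40.2,SC
ip24,10.40.3,SC
ip24,10.41.0,SD
ip24,10.41.1,SD
ip24,10.41.2,SD
ip24,10.41.3,SD
ip24,10.42.0,TN
ip24,10.42.1,TN
ip24,10.42.2,TN
ip24,10.42.3,TN
ip24,10.43.0,TX
ip24,10.43.1,TX
ip24,10.43.2,TX
ip24,10.43.3,TX
ip24,10.44.0,UT
ip24,10.44.1,UT
ip24,10.44.2,UT
ip24,10.44.3,UT
ip24,10.45.0,VT
ip24,10.45.1,VT
ip24,10.45.2,VT
ip24,10.45.3,VT
ip24,10.46.0,VA
ip24,10.46.1,VA
ip24,10.46.2,VA
ip24,10.46.3,VA
ip24,10.47.0,WA
ip24,10.47.1,WA
ip24,10.47.2,WA
ip24,10.47.3,WA
ip24,10.48.0,WV
ip24,10.48.1,WV
ip24,10.48.2,WV
ip24,10.48.3,WV
ip24,10.49.0,WI
ip24,10.49.1,WI
ip24,10.49.2,WI
ip24,10.49.3,WI
ip24,10.5.0,CA
ip24,10.5.1,CA
ip24,10.5.2,CA
ip24,10.5.3,CA
ip24,10.50.0,WY
ip24,10.50.1,WY
ip24,10.50.2,WY
ip24,10.50.3,WY
ip24,10.6.0,CO
ip24,10.6.1,CO
ip24,10.6.2,CO
ip24,10.6.3,CO
ip24,10.7.0,CT
ip24,10.7.1,CT
ip24,10.7.2,CT
ip24,10.7.3,CT
ip24,10.8.0,DE
ip24,10.8.1,DE
ip24,10.8.2,DE
ip24,10.8.3,DE
ip24,10.9.0,FL
ip24,10.9.1,FL
ip24,10.9.2,FL
ip24,10.9.3,FL
zip3,010,AL
zip3,011,AL
zip3,012,AL
zip3,013,AL
zip3,020,AK
zip3,021,AK
zip3,022,AK
zip3,023,AK
zip3,030,AZ
zip3,031,AZ
zip3,032,AZ
zip3,033,AZ
zip3,040,AR
zip3,041,AR
zip3,042,AR
zip3,043,AR
zip3,050,CA
zip3,051,CA
zip3,052,CA
zip3,053,CA
zip3,060,CO
zip3,061,CO
zip3,062,CO
zip3,063,CO
zip3,070,CT
zip3,071,CT
zip3,072,CT
zip3,073,CT
zip3,080,DE
zip3,081,DE
zip3,082,DE
zip3,083,DE
zip3,090,FL
zip3,091,FL
zip3,092,FL
zip3,093,FL
zip3,100,GA
zip3,101,GA
zip3,102,GA
zip3,103,GA
zip3,110,HI
zip3,111,HI
zip3,112,HI
zip3,113,HI
zip3,120,ID
zip3,121,ID
zip3,122,ID
zip3,123,ID
zip3,130,IL
zip3,131,IL
zip3,132,IL
zip3,133,IL
zip3,140,IN
zip3,141,IN
zip3,142,IN
zip3,143,IN
zip3,150,IA
zip3,151,IA
zip3,152,IA
zip3,153,IA
zip3,160,KS
zip3,161,KS
zip3,162,KS
zip3,163,KS
zip3,170,KY
zip3,171,KY
zip3,172,KY
zip3,173,KY
zip3,180,LA
zip3,181,LA
zip3,182,LA
zip3,183,LA
zip3,190,ME
zip3,191,ME
zip3,192,ME
zip3,193,ME
zip3,200,MD
zip3,201,MD
zip3,202,MD
zip3,203,MD
zip3,210,MA
zip3,211,MA
zip3,212,MA
zip3,213,MA
zip3,220,MI
zip3,221,MI
zip3,222,MI
zip3,223,MI
zip3,230,MN
zip3,231,MN
zip3,232,MN
zip3,233,MN
zip3,240,MS
zip3,241,MS
zip3,242,MS
zip3,243,MS
zip3,250,MO
zip3,251,MO
zip3,252,MO
zip3,253,MO
zip3,260,MT
zip3,261,MT
zip3,262,MT
zip3,263,MT
zip3,270,NE
zip3,271,NE
zip3,272,NE
zip3,273,NE
zip3,280,NV
zip3,281,NV
zip3,282,NV
zip3,283,NV
zip3,290,NH
zip3,291,NH
zip3,292,NH
zip3,293,NH
zip3,300,NJ
zip3,301,NJ
zip3,302,NJ
zip3,303,NJ
zip3,310,NM
zip3,311,NM
zip3,312,NM
zip3,313,NM
zip3,320,NY
zip3,321,NY
zip3,322,NY
zip3,323,NY
zip3,330,NC
zip3,331,NC
zip3,332,NC
zip3,333,NC
zip3,340,ND
zip3,341,ND
zip3,342,ND
zip3,343,ND
zip3,350,OH
zip3,351,OH
zip3,352,OH
zip3,353,OH
zip3,360,OK
zip3,361,OK
zip3,362,OK
zip3,363,OK
zip3,370,OR
zip3,371,OR
zip3,372,OR
zip3,373,OR
zip3,380,PA
zip3,381,PA
zip3,382,PA
zip3,383,PA
zip3,390,RI
zip3,391,RI
zip3,392,RI
zip3,393,RI
zip3,400,SC
zip3,401,SC
zip3,402,SC
zip3,403,SC
zip3,410,SD
zip3,411,SD
zip3,412,SD
zip3,413,SD
zip3,420,TN
zip3,421,TN
zip3,422,TN
zip3,423,TN
zip3,430,TX
zip3,431,TX
zip3,432,TX
zip3,433,TX
zip3,440,UT
zip3,441,UT
zip3,442,UT
zip3,443,UT
zip3,450,VT
zip3,451,VT
zip3,452,VT
zip3,453,VT
zip3,460,VA
zip3,461,VA
zip3,462,VA
zip3,463,VA
zip3,470,WA
zip3,471,WA
zip3,472,WA
zip3,473,WA
zip3,480,WV
zip3,481,WV
zip3,482,WV
zip3,483,WV
zip3,490,WI
zip3,491,WI
zip3,492,WI
zip3,493,WI
zip3,500,WY
zip3,501,WY
zip3,502,WY
zip3,503,WY
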