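id,name,sex,origin,phc_infant,year_birth,year_arrival,group
BEA,Bea,F,wild,with,1985,2012,Bilinga
CHE,Cheeta,F,wild,without,1990,2015,Bilinga
COC,Coco,F,wild,without,1994,2012,Bilinga
NIC,Nico,M,captive,without,2001,2004,Bilinga
TIC,Tico,M,wild,without,1985,2005,Bilinga
TOM,Tom,M,wild,with,1985,2011,Bilinga
VIC,Victor,M,captive,without,1982,2006,Bilinga
AFR,Africa,F,wild,without,2000,2009,Mutamba
BON,Bongo,M,captive,with,2000,2002,Mutamba
CHA,Charly,M,captive,with,1989,2001,Mutamba
JUA,Juanito,M,captive,with,2003,2005,Mutamba
MAR,Marco,M,captive,with,1984,2001,Mutamba
TON,Toni,M,wild,with,1983,2001,Mutamba
WAT,Waty,F,captive,with,1996,2002,Mutamba
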