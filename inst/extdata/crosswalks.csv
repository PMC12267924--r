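schemeId,nationalLabel,iucnCode
iucn,EX,EX
iucn,EW,EW
iucn,RE,EX
iucn,CR,CR
iucn,EN,EN
iucn,VU,VU
iucn,NT,NT
iucn,LC,LC
iucn,DD,DD
iucn,NE,NE
english,Extinct,EX
english,Extinct in the Wild,EW
english,Regionally Extinct,EX
english,Critically Endangered,CR
english,Endangered,EN
english,Vulnerable,VU
english,Near Threatened,NT
english,Least Concern,LC
english,Data Deficient,DD
english,Not Evaluated,NE
legacy,Ausgestorben,EX
legacy,Vom Aussterben bedroht,CR
legacy,Stark gefährdet,EN
legacy,Gefährdet,VU
legacy,Vorwarnliste,NT
legacy,Ungefährdet,LC
legacy,Daten unzureichend,DD
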