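center,disease,n
FRPA1,PHT,17
FRPA1,PA,40
FRPA1,PPGL,26
FRPA1,CS,0
FRPA2,PHT,0
FRPA2,PA,0
FRPA2,PPGL,0
FRPA2,CS,11
GBGL2,PHT,49
GBGL2,PA,0
GBGL2,PPGL,0
GBGL2,CS,0
GYDR,PHT,20
GYDR,PA,8
GYDR,PPGL,19
GYDR,CS,1
GYLU,PHT,0
GYLU,PA,0
GYLU,PPGL,1
GYLU,CS,0
GYMU,PHT,0
GYMU,PA,0
GYMU,PPGL,4
GYMU,CS,0
GYWU,PHT,0
GYWU,PA,0
GYWU,PPGL,1
GYWU,CS,0
IRGA,PHT,0
IRGA,PA,0
IRGA,PPGL,0
IRGA,CS,3
ITPD,PHT,0
ITPD,PA,2
ITPD,PPGL,4
ITPD,CS,14
ITPD3,PHT,0
ITPD3,PA,8
ITPD3,PPGL,0
ITPD3,CS,1
ITTU3,PHT,20
ITTU3,PA,46
ITTU3,PPGL,2
ITTU3,CS,3
NLNI,PHT,0
NLNI,PA,0
NLNI,PPGL,6
NLNI,CS,0
PLWW,PHT,0
PLWW,PA,0
PLWW,PPGL,31
PLWW,CS,0
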