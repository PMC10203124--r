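grid_id,supplier_name,film_material,hole_diameter_um,hole_spacing_um,mesh,square_size_um,bar_metal,measured_pmax_W_cm2,censor
CF-2/1-2Cu,CF 2/1 2Cu,carbon_cflat,2,1,200,90,copper,43,none
CF312,CF312 (2/1 3Cu),carbon_cflat,2,1,300,58,copper,64,none
CF412,CF412 (2/1 4Cu),carbon_cflat,2,1,400,37,copper,96,none
CF200-Cu-UL,CF200-Cu-UL,carbon_continuous,NA,NA,200,90,copper,50,lt
FF200-Cu,FF200-Cu,formvar,NA,NA,200,90,copper,690,gt
SF200-Cu,SF200-Cu,silicon_monoxide,NA,NA,200,90,copper,690,gt
SF200-Ni,SF200-Ni,silicon_monoxide,NA,NA,200,90,nickel,690,gt
UltrAuFoil-1.2/1.3-3Au,UltrAuFoil (1.2/1.3 3Au),gold_film,1.2,1.3,300,58,gold,254,none
CF313,CF313 (1.2/1.3 3Cu),carbon_cflat,1.2,1.3,300,58,copper,50,none
CF-1.2/1.3-3Au,CF 1.2/1.3 3Au,carbon_cflat,1.2,1.3,300,58,gold,50,none
QF-2/1-2Cu,QF 2/1 2Cu,carbon_quantifoil,2,1,200,90,copper,23,none
QF-1/4-2Au,QF 1/4 2Au,carbon_quantifoil,1,4,200,90,gold,16,none
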