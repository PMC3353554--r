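id,x,y,altitude,zone
Sotos de la Albolafia,343274,4193395,92,termomediterranean
Arroyo de Rabanales,357483,4196492,109,termomediterranean
Barrio Naranjo,344300,4196752,146,termomediterranean
Asland,345252,4198511,184,termomediterranean
Algeria de la Sierra,344926,4199407,217,termomediterranean
La Palomera,342737,4198985,251,mesomediterranean
Santo Domingo,341758,4200722,368,mesomediterranean
Cuesta del 14%,341181,4201771,511,mesomediterranean
La Conejera,340584,4201852,555,mesomediterranean
Los Villares,341149,4203129,585,mesomediterranean
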