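name	value
V	-85.102892115025469
m	0.0017623265207562123
h	0.74138046072498054
j	0.74047966133893739
xr1	0.00021750584954705252
xr2	0.46985723628303377
xs	0.003307469045523983
r	2.4685462901366283e-08
s	0.99999778512643955
Nai	12.261858700016706
Ki	133.14763254985584
CaiFree	0.0001192821495780011
CaSRFree	4.1695021257365905
CassFree	0.00025906804367026304
lcc.C	0.99832796352895437
lcc.Cp	4.0559819211652733e-05
lcc.O	2.7811618705623953e-06
lcc.If	0.00012740735607421559
lcc.If2	0.0011238000298547789
lcc.ICa	4.9265330435177547e-06
lcc.IC	0.00037256157191935642
ryr.R	0.98558693846498358
ryr.O	1.4202629572439855e-07
ryr.I	2.0769484035147006e-09
ryr.RI	0.014412917429450278
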