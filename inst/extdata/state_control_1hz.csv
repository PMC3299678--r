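name,value
m,0.0038468187186872036
h,0.62383401496731317
j,0.62146950777231758
xkr,0.027299969474278207
xks,0.0043004659226478104
xtos,0.00044274608559652698
ytos,0.79660680960747798
xtof,0.0004427375157226193
ytof,0.99999578735837935
d,2.9572491805850642e-06
f,0.99509521592341155
fcaBj,0.024924067846257055
fcaBsl,0.015268909359372126
RyRr,0.89426657535627796
RyRo,8.0467617229682169e-07
RyRi,9.5139912091298216e-08
NaBj,3.4316903376540138
NaBsl,0.7487542453043553
TnCL,0.0092511597655759118
TnCHc,0.11938810654375633
TnCHm,0.0096658919490598631
CaM,0.00030738194131166161
Myoc,0.002122620088706271
Myom,0.13735779946498305
SRB,0.0022501383881114384
SLLj,0.0074786608766938163
SLLsl,0.0098934059604202911
SLHj,0.074053608821816747
SLHsl,0.1145047251848294
Csqnb,1.2258900851144825
CaSR,0.57988713422382177
Naj,8.3054244538876656
Nasl,8.3043316603933075
Nai,8.3045132236446957
Ki,120
Caj,0.00017764983737024472
Casl,0.00010667072255366235
Cai,9.0779198240032848e-05
Vm,-81.387510471566713
hL,0.16237841065275321
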