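name,value
m,0.0051151528914791461
h,0.57338909568624219
j,0.56205038576551913
xkr,0.043274285539718148
xks,0.0047357095401406634
xtos,0.00049238476772455863
ytos,0.829749165745297
xtof,0.00049232167683007158
ytof,0.99999444709045782
d,3.7211471042924161e-06
f,0.99419470053908587
fcaBj,0.047097459812864291
fcaBsl,0.018313496532215954
RyRr,0.8061476351990271
RyRo,2.381449039356882e-06
RyRi,5.7265254245394935e-07
NaBj,3.5749441666291126
NaBsl,0.77937328387680349
TnCL,0.0099483329307356143
TnCHc,0.11883904678057423
TnCHm,0.0099552352085898067
CaM,0.00033046147746288693
Myoc,0.0021139903790740782
Myom,0.13737026926449442
SRB,0.0024028485266522951
SLLj,0.01426346248899577
SLLsl,0.011831120562944109
SLHj,0.10622683700502893
SLHsl,0.13049219356880143
Csqnb,1.0863876224984084
CaSR,0.46653394718109525
Naj,8.9710953472788937
Nasl,8.9545223102381204
Nai,8.9544740715150972
Ki,120
Caj,0.00034305721832697018
Casl,0.00012776180347925608
Cai,9.758831233184546e-05
Vm,-80.009014372233395
hL,0.10996398547896061
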