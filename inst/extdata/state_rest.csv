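name,value
m,0.0041861273443025201
h,0.60934140775360668
j,0.6093415686309166
xkr,6.8351886749821879e-07
xks,0.0044245887259681668
xtos,0.00045681609397744597
ytos,0.99999543010436398
xtof,0.00045681609996554102
ytof,0.99999543007467295
d,3.1650425700129315e-06
f,0.99485123210117732
fcaBj,0.01971662575674045
fcaBsl,0.012275275624441964
RyRr,0.90169962612355481
RyRo,3.8472945961329789e-07
RyRi,4.1941778029630756e-08
NaBj,3.0418413158118951
NaBsl,0.66367630738119654
TnCL,0.0074457034709797332
TnCHc,0.102961839089858
TnCHm,0.017553613220038303
CaM,0.00024213972864221321
Myoc,0.0010756371805668403
Myom,0.13842181174357276
SRB,0.0018172215245285265
SLLj,0.0059434625681968689
SLLsl,0.0080799396297867639
SLHj,0.063555528440087106
SLHsl,0.097898542577114389
Csqnb,1.0821486568375358
CaSR,0.46341601900725282
Naj,6.7308914133586626
Nasl,6.7286890594164834
Nai,6.7286912160035648
Ki,120
Caj,0.0001407922190380474
Casl,8.6994756830746051e-05
Cai,7.1343884727458095e-05
Vm,-80.980045306525085
hL,0.1621097100461466
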