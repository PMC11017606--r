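sex,age_group_start,a,b,c,v
male,0,-0.09705033141,1.079121338e+00,6.698594022e-03,-0.005752227477
male,1,-2.42348058396,1.114329848e+00,1.283787698e-02,0.014291440099
male,5,-6.62419408404,1.162211927e+00,8.893134458e-02,0.747706314803
male,10,-9.09777063972,2.496042339e-02,2.404287593e-03,1.300629765432
male,15,-8.61214650783,1.296190172e-04,1.252197605e-05,1.307800373648
male,20,-8.42975431570,9.343346982e-07,9.026369403e-08,1.307837169863
male,25,-8.27103052171,6.896459299e-09,6.662347169e-10,1.307837435042
male,30,-8.05319209822,4.713148304e-11,4.534949619e-12,1.307837437000
male,35,-7.75629568617,-3.410009396e-13,-4.648581614e-14,1.307837437014
male,40,-7.38043741780,-7.010923582e-13,-8.264145091e-14,1.307837437014
male,45,-6.93784149693,-6.993955501e-13,-8.264145091e-14,1.307837437014
male,50,-6.44585806940,-7.002791411e-13,-8.264145091e-14,1.307837437014
male,55,-5.92079219701,-5.487438095e-13,-6.456363353e-14,1.307837437014
male,60,-5.37502696508,-5.684404998e-13,-6.714617887e-14,1.307837437014
male,65,-4.86246467927,-3.971837497e-13,-4.648581614e-14,1.260609974011
male,70,-4.38827038353,-4.393418409e-13,-5.165090682e-14,1.166155048004
male,75,-3.90991935109,-3.950672911e-13,-4.648581614e-14,1.071700121998
male,80,-3.42920158678,-3.509825313e-13,-4.132072546e-14,0.977245195991
male,85,-2.94714314647,-2.639118687e-13,-3.099054409e-14,0.882790269985
male,90,-2.46432745848,-2.416110982e-13,-2.840799875e-14,0.788335343978
male,95,-1.98108475920,-1.875140916e-13,-2.195163540e-14,0.693880417971
male,100,-1.49760149151,-1.220187311e-13,-1.420399938e-14,0.599425491965
male,105,-1.01398276376,-6.702891921e-14,-7.747636023e-15,0.504970565958
male,110,-0.42719140706,-2.066661305e-14,-2.259727173e-15,0.457743102955
female,0,-0.10091930709,1.077803918e+00,6.590701191e-03,-0.005725081416
female,1,-2.42755592860,1.112860559e+00,1.270325162e-02,0.014231155606
female,5,-6.62613901932,1.162442617e+00,8.887324219e-02,0.746560983844
female,10,-9.10594026200,2.512403200e-02,2.419850423e-03,1.300578604458
female,15,-8.62264910406,1.307529396e-04,1.263077260e-05,1.307800174738
female,20,-8.44014375493,9.423997675e-07,9.103744527e-08,1.307837310822
female,25,-8.27642953511,6.920288404e-09,6.684712012e-10,1.307837578429
female,30,-8.04537727523,4.589072322e-11,4.395492170e-12,1.307837580396
female,35,-7.72514390733,-1.457311330e-12,-1.807781739e-13,1.307837580409
female,40,-7.31698456621,-1.430068220e-12,-1.704479925e-13,1.307837580409
female,45,-6.83656902401,-1.473446549e-12,-1.756130832e-13,1.307837580409
female,50,-6.30472257472,-1.344007532e-12,-1.601178111e-13,1.307837580409
female,55,-5.73989625729,-1.214053212e-12,-1.446225391e-13,1.307837580409
female,60,-5.15532487684,-1.170854903e-12,-1.394574484e-13,1.307837580409
female,65,-4.60502098251,-9.754213391e-13,-1.162145403e-13,1.260610112228
female,70,-4.09396921350,-8.667961795e-13,-1.033018136e-13,1.166155175865
female,75,-3.57940762137,-7.592798201e-13,-9.038908694e-14,1.071700239502
female,80,-3.06292123006,-6.294338760e-13,-7.489381489e-14,0.977245303139
female,85,-2.54538370215,-4.998136717e-13,-5.939854284e-14,0.882790366776
female,90,-2.02727346519,-3.916122806e-13,-4.648581614e-14,0.788335430413
female,95,-1.50885158030,-3.321147644e-13,-3.938381645e-14,0.693880494051
female,100,-0.99026022342,-1.859374308e-13,-2.195163540e-14,0.599425557688
female,105,-0.47157674304,-7.249285277e-14,-8.393272358e-15,0.504970621325
female,110,0.15375604298,4.643633841e-14,5.810727017e-15,0.457743153143
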