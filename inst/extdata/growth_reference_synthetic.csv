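"sex","age_months","L","M","S"
"female",24,-1.8,16.4156866895815,0.085
"female",36,-1.75555555555556,16.1211910460166,0.0877777777777778
"female",48,-1.71111111111111,15.840948882488,0.0905555555555556
"female",60,-1.66666666666667,15.8128388558593,0.0933333333333333
"female",72,-1.62222222222222,16.1731317318202,0.0961111111111111
"female",84,-1.57777777777778,16.7756493125748,0.0988888888888889
"female",96,-1.53333333333333,17.3640367625297,0.101666666666667
"female",108,-1.48888888888889,17.8208566043408,0.104444444444444
"female",120,-1.44444444444444,18.1807156076,0.107222222222222
"female",132,-1.4,18.5105420433946,0.11
"female",144,-1.35555555555556,18.8469954998226,0.112777777777778
"female",156,-1.31111111111111,19.2011949114122,0.115555555555556
"female",168,-1.26666666666667,19.5748570097478,0.118333333333333
"female",180,-1.22222222222222,19.9676537189049,0.121111111111111
"female",192,-1.17777777777778,20.3790148248964,0.123888888888889
"female",204,-1.13333333333333,20.8083997659436,0.126666666666667
"female",216,-1.08888888888889,21.2553175149533,0.129444444444444
"female",228,-1.04444444444444,21.7193208218308,0.132222222222222
"female",240,-1,22.2,0.135
"male",24,-1.8,16.2156866895815,0.085
"male",36,-1.75555555555556,15.9211910460166,0.0877777777777778
"male",48,-1.71111111111111,15.640948882488,0.0905555555555556
"male",60,-1.66666666666667,15.6128388558593,0.0933333333333333
"male",72,-1.62222222222222,15.9731317318202,0.0961111111111111
"male",84,-1.57777777777778,16.5756493125748,0.0988888888888889
"male",96,-1.53333333333333,17.1640367625297,0.101666666666667
"male",108,-1.48888888888889,17.6208566043408,0.104444444444444
"male",120,-1.44444444444444,17.9807156076,0.107222222222222
"male",132,-1.4,18.3105420433946,0.11
"male",144,-1.35555555555556,18.6469954998226,0.112777777777778
"male",156,-1.31111111111111,19.0011949114122,0.115555555555556
"male",168,-1.26666666666667,19.3748570097478,0.118333333333333
"male",180,-1.22222222222222,19.7676537189049,0.121111111111111
"male",192,-1.17777777777778,20.1790148248964,0.123888888888889
"male",204,-1.13333333333333,20.6083997659436,0.126666666666667
"male",216,-1.08888888888889,21.0553175149533,0.129444444444444
"male",228,-1.04444444444444,21.5193208218308,0.132222222222222
"male",240,-1,22,0.135
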