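name,form,direction,intercept,slope,source
rice_2007,linear,sf_from_pf,64,0.84,"Rice TW et al., Chest 2007;132(2):410-417 (SF = 64 + 0.84 PF, SpO2 <= 97%)"
bilan_2015,linear,sf_from_pf,57,0.61,"Bilan N et al., J Cardiovasc Thorac Res 2015;7(1):28-31 (SF = 57 + 0.61 PF)"
severinghaus_loglinear_synthetic,loglinear,sf_from_pf,1.073677,0.8472634,"synthetic: log-linear least-squares fit to noise-free Severinghaus-curve data (SpO2 <= 97%, PF 50-300) generated by this package"
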