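term,gloss,ll,a,b
causa,cause,0.063,48,2
social,social,0.051,36,1
difundir,promulgate,0.047,23,1
medio,middle/way,0.031,24,1
experiencias,experiences,0.027,34,1
forma,form,0.021,52,2
general,general,0.01,32,1
cuanto,how much,0.01,26,1
todas,all,0.007,91,3
dice,says,0.000014,29,1
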