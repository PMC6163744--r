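term,gloss,ll,a,b
nacional,national,20.2,32,9
discapacidad,disability,13.4,53,9
nivel,level,7.8,28,5
ayuda,help,7.5,195,1
profesionales,professionals,6.1,23,4
referencia,reference,5.0,28,4
vida,life,4.3,190,2
frecuentes,frequents,3.8,35,4
enfermedades,diseases,3.3,192,12
ser,to be,3.2,167,2
personas,people,3.0,206,3
hijo,son,3.0,112,1
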