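term,polarity,subjectivity,role,factor
feliz,0.9,0.9,term,
alegria,0.8,0.8,term,
maravilloso,0.9,0.9,term,
estupendo,0.8,0.8,term,
genial,0.8,0.8,term,
animo,0.5,0.7,term,
esperanza,0.6,0.7,term,
carino,0.6,0.8,term,
abrazo,0.5,0.7,term,
bonito,0.7,0.8,term,
bueno,0.6,0.6,term,
mejor,0.5,0.5,term,
enhorabuena,0.9,0.9,term,
gracias,0.8,0.9,term,
agradecida,0.7,0.8,term,
triste,-0.7,0.8,term,
tristeza,-0.7,0.8,term,
miedo,-0.6,0.7,term,
dolor,-0.6,0.6,term,
horrible,-0.9,0.9,term,
terrible,-0.9,0.9,term,
peor,-0.5,0.5,term,
dificil,-0.4,0.5,term,
preocupada,-0.5,0.7,term,
crisis,-0.5,0.4,term,
malo,-0.6,0.6,term,
cansada,-0.4,0.6,term,
angustia,-0.7,0.8,term,
happy,0.8,1.0,term,
dear,0.6,0.8,term,
interesting,0.5,0.5,term,
wonderful,0.9,0.9,term,
good,0.7,0.6,term,
great,0.8,0.75,term,
thanks,0.7,0.8,term,
sad,-0.7,0.8,term,
dreadful,-0.9,0.9,term,
crises,-0.6,0.5,term,
awful,-0.9,0.9,term,
bad,-0.7,0.7,term,
painful,-0.6,0.7,term,
no,,,negator,
nunca,,,negator,
jamas,,,negator,
not,,,negator,
never,,,negator,
muy,1.3,,intensifier,1.3
tan,1.2,,intensifier,1.2
very,1.3,,intensifier,1.3
really,1.25,,intensifier,1.25
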