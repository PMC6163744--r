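a
al
algo
algunas
algunos
ante
antes
como
con
contra
cual
cuando
de
del
desde
donde
durante
e
el
ella
ellas
ellos
en
entre
era
eres
es
esa
esas
ese
eso
esos
esta
estas
este
esto
estos
fue
ha
han
hasta
hay
la
las
le
les
lo
los
mas
me
mi
mis
mucho
muchos
muy
nada
ni
no
nos
nosotros
nuestra
nuestro
o
os
otra
otros
para
pero
poco
por
porque
que
quien
se
sea
segun
ser
si
sin
sobre
son
su
sus
tambien
tanto
te
tiene
tienen
todo
todos
tu
tus
un
una
uno
unas
unos
vosotros
y
ya
yo
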