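word	transcription
baran	baran
batew	batew
behoj	behoj
benus	benus
besah	besah
bidib	bidib
biheh	biheh
bimap	bimap
bisin	bisin
bocan	bocan
bonot	bonot
bosaw	bosaw
boseh	boseh
boter	boter
bovid	bovid
cagig	cagig
cahar	cahar
catet	catet
cecen	cecen
cenes	cenes
cenup	cenup
ceteh	ceteh
ceweh	ceweh
cidet	cidet
cilil	cilil
cinep	cinep
citar	citar
coceh	coceh
cofav	cofav
conew	conew
cotur	cotur
cutar	cutar
cuten	cuten
dacet	dacet
dacor	dacor
dagov	dagov
datag	datag
decet	decet
deguc	deguc
dehag	dehag
dehal	dehal
dehel	dehel
dereh	dereh
detel	detel
detod	detod
didil	didil
dihid	dihid
dilis	dilis
disel	disel
dohat	dohat
dolah	dolah
dowag	dowag
duhen	duhen
dupet	dupet
dutut	dutut
duweh	duweh
duwon	duwon
fapoh	fapoh
fedas	fedas
fediw	fediw
fegeh	fegeh
fegen	fegen
fehon	fehon
felol	felol
fenow	fenow
feres	feres
ferid	ferid
fesul	fesul
fewof	fewof
fibag	fibag
fiser	fiser
fitat	fitat
fitir	fitir
fiwur	fiwur
focel	focel
forip	forip
fucen	fucen
fudas	fudas
fuhok	fuhok
fupob	fupob
gaset	gaset
geler	geler
genen	genen
genor	genor
getof	getof
gifet	gifet
gigas	gigas
giged	giged
gihet	gihet
gitik	gitik
gocar	gocar
godom	godom
gosan	gosan
gotal	gotal
gusol	gusol
hafem	hafem
hagih	hagih
hahos	hahos
halun	halun
hares	hares
hatod	hatod
hawor	hawor
hegit	hegit
hehob	hehob
hehor	hehor
helad	helad
helet	helet
hemaw	hemaw
henes	henes
henir	henir
hesed	hesed
hesel	hesel
hesim	hesim
hesor	hesor
hetam	hetam
hetoh	hetoh
hetos	hetos
hetot	hetot
hetun	hetun
hidef	hidef
hihih	hihih
hinoc	hinoc
hinow	hinow
hobes	hobes
holes	holes
holon	holon
homat	homat
honag	honag
horet	horet
hotef	hotef
hovar	hovar
hufod	hufod
hugil	hugil
husot	husot
hutam	hutam
jadad	jadad
jahic	jahic
jahir	jahir
jutar	jutar
kadan	kadan
kehek	kehek
kelas	kelas
ladel	ladel
lahed	lahed
lalit	lalit
lamet	lamet
lamom	lamom
latad	latad
latet	latet
lawop	lawop
lebat	lebat
legab	legab
leher	leher
lelod	lelod
lelot	lelot
lelur	lelur
lemuf	lemuf
leped	leped
lerel	lerel
leres	leres
lesim	lesim
lesit	lesit
letag	letag
lewih	lewih
lidar	lidar
lihor	lihor
liner	liner
liral	liral
liram	liram
liret	liret
lisas	lisas
liten	liten
liter	liter
lofit	lofit
lohen	lohen
lohos	lohos
lonaw	lonaw
lonep	lonep
losak	losak
loses	loses
lowas	lowas
lutan	lutan
luter	luter
maban	maban
manim	manim
maniw	maniw
maruf	maruf
masel	masel
masis	masis
matun	matun
mawet	mawet
medot	medot
megan	megan
mehac	mehac
mehut	mehut
memot	memot
merep	merep
meriw	meriw
mivan	mivan
momos	momos
morah	morah
motas	motas
mufos	mufos
naben	naben
nacaf	nacaf
nadar	nadar
nafip	nafip
nagoh	nagoh
naheh	naheh
nahit	nahit
namel	namel
nanal	nanal
nanec	nanec
napos	napos
narig	narig
navos	navos
nawec	nawec
nawof	nawof
nedas	nedas
nedut	nedut
nefen	nefen
negeh	negeh
nehan	nehan
nehon	nehon
nelaf	nelaf
nelet	nelet
nemeh	nemeh
nemes	nemes
nemis	nemis
nenaf	nenaf
nenas	nenas
nenes	nenes
nenil	nenil
neniw	neniw
nepor	nepor
neriv	neriv
nesas	nesas
nesec	nesec
nesit	nesit
nesos	nesos
netal	netal
netel	netel
nevom	nevom
newur	newur
nicit	nicit
nifup	nifup
ninat	ninat
nined	nined
nirem	nirem
nitas	nitas
nitew	nitew
niwan	niwan
nocas	nocas
nofas	nofas
noher	noher
nohon	nohon
nonet	nonet
nopes	nopes
nopet	nopet
nosef	nosef
notan	notan
notoh	notoh
nowid	nowid
nufol	nufol
nugon	nugon
numid	numid
nurew	nurew
padet	padet
pasel	pasel
peneh	peneh
pesol	pesol
pihit	pihit
pilet	pilet
ponop	ponop
ponul	ponul
posed	posed
rafir	rafir
ranes	ranes
ranet	ranet
rasum	rasum
ratan	ratan
ratet	ratet
ratew	ratew
rawos	rawos
recih	recih
recom	recom
redet	redet
rehab	rehab
rehan	rehan
reheh	reheh
rehen	rehen
remar	remar
renan	renan
renit	renit
rerer	rerer
resoh	resoh
retar	retar
retot	retot
rever	rever
rewel	rewel
rewod	rewod
ridaw	ridaw
rifut	rifut
rijus	rijus
rilet	rilet
rilot	rilot
rinas	rinas
rinod	rinod
ripom	ripom
rireh	rireh
risap	risap
risem	risem
risit	risit
riton	riton
ronol	ronol
ronon	ronon
rorad	rorad
rotej	rotej
rotil	rotil
rotob	rotob
rowed	rowed
rucar	rucar
rufem	rufem
rumon	rumon
rurej	rurej
sadev	sadev
safic	safic
sanas	sanas
sapet	sapet
sapiv	sapiv
sasec	sasec
saseg	saseg
saser	saser
sases	sases
satob	satob
secol	secol
secop	secop
segol	segol
sehem	sehem
sehes	sehes
sehir	sehir
selat	selat
selil	selil
semad	semad
semon	semon
senar	senar
senih	senih
senoc	senoc
seret	seret
sesar	sesar
seten	seten
sewid	sewid
sidim	sidim
sidow	sidow
sifof	sifof
sihan	sihan
sihin	sihin
silac	silac
silig	silig
siner	siner
sipot	sipot
sirad	sirad
sireb	sireb
sired	sired
sirev	sirev
sisur	sisur
sobas	sobas
sofem	sofem
sohel	sohel
sohor	sohor
solod	solod
soteg	soteg
sotet	sotet
sovun	sovun
sowit	sowit
suduc	suduc
suhig	suhig
tadaf	tadaf
tagid	tagid
tahen	tahen
takih	takih
talen	talen
taned	taned
tanor	tanor
tarih	tarih
taseh	taseh
tatah	tatah
tatat	tatat
tatet	tatet
tatot	tatot
tebes	tebes
tebus	tebus
tecar	tecar
tedit	tedit
tedol	tedol
tedos	tedos
tefen	tefen
tehon	tehon
telet	telet
telok	telok
tenad	tenad
tener	tener
tenos	tenos
teraf	teraf
terop	terop
tetec	tetec
teted	teted
tetog	tetog
tetor	tetor
tetot	tetot
tetuh	tetuh
teves	teves
tevib	tevib
tidan	tidan
tideh	tideh
tidin	tidin
tifeh	tifeh
tigif	tigif
tigij	tigij
tigow	tigow
tihac	tihac
tihav	tihav
tiheh	tiheh
tihis	tihis
tinah	tinah
tinat	tinat
tinaw	tinaw
tiner	tiner
tinet	tinet
tinig	tinig
tinon	tinon
tipic	tipic
tiset	tiset
tisil	tisil
titel	titel
titet	titet
tivaw	tivaw
tiwev	tiwev
tiwig	tiwig
toden	toden
tofos	tofos
toget	toget
tohec	tohec
tokar	tokar
tomem	tomem
tonip	tonip
torew	torew
tosil	tosil
totes	totes
toweg	toweg
tucit	tucit
tudot	tudot
tulut	tulut
tunen	tunen
tusal	tusal
tusil	tusil
tuteh	tuteh
tutih	tutih
tutuh	tutuh
tuwen	tuwen
vadof	vadof
varut	varut
vebak	vebak
vegud	vegud
vehas	vehas
vehoh	vehoh
venel	venel
vesaf	vesaf
vipom	vipom
viric	viric
vitic	vitic
vohel	vohel
vohot	vohot
vorew	vorew
vosit	vosit
vurad	vurad
vusep	vusep
wades	wades
wahas	wahas
waheg	waheg
wapac	wapac
wawoh	wawoh
weben	weben
weden	weden
wegas	wegas
welus	welus
wener	wener
wepiv	wepiv
werat	werat
wetan	wetan
wifit	wifit
wihih	wihih
wirah	wirah
wisol	wisol
witip	witip
wobum	wobum
wofes	wofes
wuher	wuher
wuhir	wuhir
wunil	wunil
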