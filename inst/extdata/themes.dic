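%
1	clout
2	tone
3	first_person_plural
4	mental_health
5	pregnancy_health
6	want
7	space
8	time
9	perception
10	third_person_singular
11	impersonal_pronouns
12	causation
13	covid
%
we	1 3
our	1 3
us	1 3
ours	3
ourselves	3
lets	3
you	1
your	1
everyone	1
everybody	1
leader*	1
confident*	1
sure	1
proud	1 2
happ*	2
glad	2
excit*	2
wonderful	2
great	2
love*	2
joy*	2
grateful	2
amazing	2
good	2
beautiful	2
calm*	2
peaceful	2
blessed	2
thrill*	2
delight*	2
cheer*	2
content	2
smil*	2
sad*	2
worri*	2
scared	2
awful	2
terrible	2
cry*	2
angry	2
stress*	2
upset	2
miserable	2
lonel*	2
afraid	2
frustrat*	2
nervous	2
gloomy	2
hurt	2
fear*	2
tearful	2
therap*	4
psychiatr*	4
antidepressant*	4
zoloft	4
depress*	4
anxi*	4
panic	4
trauma*	4
counsel*	4
medication*	4
suicid*	4
mental	4
pregnan*	5
trimester	5
midwife	5
heartburn	5
contraction*	5
nausea	5
swelling	5
cramp*	5
doula	5
amniocentesis	5
cervix	5
braxton	5
ultrasound	5
want*	6
wish*	6
hope*	6
wanna	6
crav*	6
desire*	6
need*	6
longing	6
home	7
house	7
room	7
inside	7
outside	7
around	7
upstairs	7
indoors	7
place	7
apartment	7
staying	7
stuck	7
in	7
out	7
here	7
today	8
week	8
day	8
now	8
then	8
soon	8
later	8
finally	8
month	8
morning	8
evening	8
ever	8
never	8
yesterday	8
tomorrow	8
time	8
feel*	9
see*	9
hear*	9
look*	9
watch*	9
smell*	9
taste*	9
touch*	9
she	10
he	10
her	10
him	10
his	10
hers	10
herself	10
himself	10
it	11
that	11
this	11
those	11
these	11
everything	11
something	11
anything	11
nothing	11
what	11
other	11
because	12
how	12
why	12
since	12
therefore	12
make*	12
cause*	12
result*	12
reason*	12
effect*	12
covid*	13
mask*	13
booster*	13
vaccin*	13
pandemic	13
quarantine	13
isolat*	13
virus	13
corona*	13
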