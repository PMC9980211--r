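ach	0.016	0.868
afraid	0.096	0.789
alright	0.296	0.086
amaz	0.567	0.058
angri	0.038	0.766
anguish	0.021	0.743
annoi	0.098	0.595
annoi	0.035	0.857
aw	0.004	0.587
awesom	0.694	0.021
awkward	0.03	0.546
beauti	0.615	0.029
bless	0.873	0.092
bright	0.876	0.077
busi	0.091	0.271
busi	0.146	0.236
calm	0.565	0.073
calm	0.382	0.136
cheer	0.523	0.1
comfort	0.758	0.048
content	0.861	0.073
content	0.53	0.136
cry	0.091	0.666
cry	0.07	0.848
delight	0.734	0.023
despair	0.031	0.899
dread	0.006	0.612
dread	0.089	0.853
enjoi	0.796	0.084
enjoi	0.85	0.059
excit	0.695	0.084
exhaust	0.084	0.687
fast	0.233	0.203
fear	0.041	0.836
fine	0.26	0.205
frustrat	0.068	0.802
fun	0.609	0.058
glad	0.707	0.083
gloomi	0.041	0.702
good	0.836	0.079
grate	0.531	0.061
great	0.601	0.025
grumpi	0.021	0.776
guilti	0.093	0.654
happi	0.533	0.082
healthi	0.828	0.091
horribl	0.009	0.57
hurt	0.016	0.711
hurt	0.108	0.456
interest	0.056	0.12
irrit	0.089	0.851
joi	0.862	0.01
laugh	0.804	0.01
laugh	0.763	0.018
lone	0.03	0.653
love	0.865	0.041
love	0.636	0.06
miser	0.08	0.753
moodi	0.05	0.563
nervou	0.043	0.707
nice	0.55	0.036
okai	0.142	0.283
optimist	0.854	0.04
pain	0.071	0.595
pain	0.073	0.673
peac	0.818	0.002
perfect	0.66	0.097
plain	0.242	0.224
pleasant	0.688	0.01
proud	0.549	0.066
quiet	0.218	0.1
reassur	0.779	0.025
relax	0.823	0.01
reliev	0.733	0.063
sad	0.082	0.625
scare	0.012	0.556
sick	0.071	0.58
simpl	0.139	0.185
slow	0.079	0.121
smile	0.783	0.047
smile	0.8	0.004
stress	0.026	0.563
stress	0.07	0.845
support	0.9	0.067
sweet	0.585	0.082
tear	0.006	0.567
terribl	0.039	0.885
thrill	0.801	0.027
unhappi	0.099	0.814
upset	0.027	0.848
weep	0.019	0.883
wonder	0.891	0.084
worri	0.067	0.56
worst	0.086	0.849
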