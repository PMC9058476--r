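molecule_id,atom_index,element,net_charge,hirshfeld_like,mep_like,stockholder_like,projection_like
mol00001,0,C,0,0.14287,0.374315,0.301634,0.363831
mol00001,1,C,0,-0.182347,-0.369478,-0.419611,-0.741672
mol00001,2,C,0,0.053314,0.064884,0.099768,0.522313
mol00001,3,C,0,-0.080737,-0.131602,-0.023744,-0.028004
mol00001,4,C,0,0.0669,0.061881,0.041953,-0.116469
mol00002,0,C,0,0.17959,0.432319,0.420714,0.646352
mol00002,1,C,0,0.109011,0.179801,0.217562,0.511198
mol00002,2,C,0,-0.063665,-0.038517,-0.107594,-0.339747
mol00002,3,C,0,-0.049081,-0.200394,-0.11442,-0.202742
mol00002,4,C,0,-0.175855,-0.373208,-0.416263,-0.615061
mol00003,0,C,0,-0.06353,-0.136462,-0.109906,-0.232584
mol00003,1,C,0,-0.010161,-0.02007,-0.005191,-0.109534
mol00003,2,C,0,0.073691,0.156532,0.115097,0.342118
mol00004,0,C,0,-0.049294,-0.160711,-0.156743,-0.702816
mol00004,1,C,0,-0.060547,-0.19239,-0.236688,-0.183373
mol00004,2,C,0,-0.10222,-0.261996,-0.244125,-0.007307
mol00004,3,C,0,0.104448,0.334524,0.338015,0.63389
mol00004,4,C,0,0.107613,0.280573,0.29954,0.259607
mol00005,0,C,0,0.005508,0.002865,0.073178000000000007,0.062533
mol00005,1,C,0,-0.005508,-0.002865,-0.073178000000000007,-0.062533
mol00006,0,C,0,-0.111606,-0.283098,-0.223316,-0.292246
mol00006,1,C,0,0.111606,0.283098,0.223316,0.292246
mol00007,0,C,0,0.156696,0.335932,0.270097,0.255256
mol00007,1,C,0,-0.156696,-0.335932,-0.270097,-0.255256
mol00008,0,C,0,0.074955,0.146647,0.251606,0.326076
mol00008,1,C,0,-0.11869,-0.318605,-0.38845,-0.462626
mol00008,2,C,0,0.099862,0.287309,0.312325,0.407014
mol00008,3,C,0,-0.133024,-0.407234,-0.413553,-0.51445
mol00008,4,C,0,0.076897,0.291883,0.238071,0.243986
mol00009,0,C,0,-0.058874,0.010737,-0.047046,-0.017616
mol00009,1,C,0,0.1645,0.385593,0.422584,0.417857
mol00009,2,C,0,-0.105626,-0.39633,-0.375537,-0.400241
mol00010,0,C,0,0.113527,0.22142,0.252182,0.468396
mol00010,1,C,0,-0.019564,0.03846,0.015125,0.116323
mol00010,2,C,0,0.126545,0.259072,0.253669,0.553667
mol00010,3,C,0,0.026702,-0.097423,-0.084825,-0.394411
mol00010,4,C,0,-0.24721,-0.42153,-0.436151,-0.743976
mol00011,0,C,0,0.051466,0.081226,0.084531,0.018885
mol00011,1,C,0,-0.068984,-0.131835,-0.137844,-0.055069
mol00011,2,C,0,0.017518,0.050609,0.053312,0.036185
mol00012,0,C,0,-0.084038,-0.095621,-0.163036,-0.237957
mol00012,1,C,0,-0.075332,-0.183772,-0.134295,-0.355926
mol00012,2,C,0,0.124735,0.278909,0.27423,0.588513
mol00012,3,C,0,0.034635,4.84e-4,0.023101,0.00537
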