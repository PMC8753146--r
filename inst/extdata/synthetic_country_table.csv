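country,iso3,democracy_index,cpi,freedom_score,control_of_corruption,turnout_avg,gdp_pc,eu_member,population
Synthetic country 001,S01,9.45,88,92,0.87,46.5,36529,1,1561625
Synthetic country 002,S02,3.33,28,40,0,55.3,4271,0,723068
Synthetic country 003,S03,9.17,96,93,1.54,46.6,95611,1,5870920
Synthetic country 004,S04,5.08,9,41,-1.3,65.9,7232,0,687894
Synthetic country 005,S05,5.83,33,73,-0.23,68.5,15422,1,73638917
Synthetic country 006,S06,6.7,72,67,0.82,61.3,13654,1,1201223
Synthetic country 007,S07,1.42,0,12,-2.5,84.1,1090,0,14613307
Synthetic country 008,S08,1.84,19,18,-1.05,75.3,2715,0,293656
Synthetic country 009,S09,1.82,32,24,-0.14,73.6,8790,0,5415864
Synthetic country 010,S10,4.47,29,46,-0.15,76.9,1350,1,1975101
Synthetic country 011,S11,5.11,49,33,-0.16,57.9,18001,1,7103409
Synthetic country 012,S12,4.38,44,51,0.14,63.5,37051,1,393099
Synthetic country 013,S13,2.37,26,25,-1.2,67,1983,1,2402338
Synthetic country 014,S14,6.19,91,61,0.69,57.5,4279,1,207386
Synthetic country 015,S15,4.17,6,48,-0.84,74.2,1811,1,721738
Synthetic country 016,S16,0.68,33,19,-0.16,78.1,1953,0,14816735
Synthetic country 017,S17,9.35,83,91,0.73,52,4732,1,1760878
Synthetic country 018,S18,2.28,51,36,0.6,60.6,44266,1,817152
Synthetic country 019,S19,7.22,47,62,-0.19,63.7,7979,1,11912404
Synthetic country 020,S20,2.52,65,27,-0.13,71.2,6289,1,57353805
Synthetic country 021,S21,7.37,59,72,0.28,56.7,21495,1,1006493
Synthetic country 022,S22,2.83,44,33,-0.47,70,8701,1,142922963
Synthetic country 023,S23,8.88,76,78,0.8,54.8,42304,1,8469684
Synthetic country 024,S24,4.09,64,33,-0.19,57.3,45104,0,686294
Synthetic country 025,S25,7.36,40,68,-0.07,59.6,17122,0,2369470
Synthetic country 026,S26,2.26,7,33,-1.3,80.3,4190,0,5961098
Synthetic country 027,S27,3,28,36,-0.48,60.1,9920,0,179998
Synthetic country 028,S28,1.28,13,13,-0.78,77.6,609,0,6015080
Synthetic country 029,S29,0.03,1,1,-2.43,90,595,0,5668940
Synthetic country 030,S30,3.26,27,31,-0.46,77.2,2014,0,2045838
Synthetic country 031,S31,3.73,41,27,0.14,75.2,2365,0,86986715
Synthetic country 032,S32,9.94,94,97,1.54,48.8,100260,1,2310471
Synthetic country 033,S33,8.77,94,82,1.32,56.7,6040,1,8495706
Synthetic country 034,S34,8,87,80,0.94,55.3,89060,1,1554450
Synthetic country 035,S35,2.63,14,43,-0.97,81.1,899,1,4266565
Synthetic country 036,S36,0.39,3,8,-1.93,97.9,1115,1,296359865
Synthetic country 037,S37,2.53,18,44,-0.93,67.8,2219,1,259880
Synthetic country 038,S38,8.29,89,78,0.78,52.4,26706,1,1151531
Synthetic country 039,S39,8.23,54,85,-0.17,56.7,3596,1,1072138
Synthetic country 040,S40,9.07,66,91,0.77,48.6,32196,0,4438977
Synthetic country 041,S41,8.42,21,79,-0.81,71.3,4487,1,3629111
Synthetic country 042,S42,0.06,6,1,-1.21,79.6,1467,0,983018
Synthetic country 043,S43,7.85,71,73,0.59,52.5,17176,0,3681501
Synthetic country 044,S44,3.4,36,35,-0.32,65,22807,0,389985
Synthetic country 045,S45,2.17,15,42,-0.6,68.4,2989,0,373718
Synthetic country 046,S46,5.8,51,58,-0.15,54.2,9206,0,933784
Synthetic country 047,S47,9.38,81,91,1.25,56.2,22313,1,1846841
Synthetic country 048,S48,9.2,81,93,0.77,46.5,109331,1,13485301
Synthetic country 049,S49,6.15,85,62,0.93,57.4,9955,0,5039139
Synthetic country 050,S50,4.38,35,35,-0.97,75.2,4367,1,28613664
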