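NAME: TMAO
FORMULA: C3H9NO
EXACTMASS: 75.0684
RETENTIONTIME: 1.32
SOURCE: in_house
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 3
58.0651 100
59.0730 35
75.0684 60

NAME: 5-AVAB
FORMULA: C8H17NO2
EXACTMASS: 159.1259
RETENTIONTIME: 1.85
SOURCE: in_house
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 4
60.0808 100
100.1121 45
142.1226 30
159.1259 20

NAME: Hippuric acid
FORMULA: C9H9NO3
EXACTMASS: 179.0582
RETENTIONTIME: 4.10
SOURCE: in_house
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 3
77.0386 60
105.0335 100
134.0600 25

NAME: Pipecolic acid
FORMULA: C6H11NO2
EXACTMASS: 129.0790
RETENTIONTIME: 1.55
SOURCE: in_house
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 3
56.0495 70
84.0808 100
129.0790 15

NAME: Kynurenine
FORMULA: C10H12N2O3
EXACTMASS: 208.0848
RETENTIONTIME: 3.25
SOURCE: in_house
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 4
94.0651 80
146.0600 100
174.0550 40
192.0655 30

NAME: 3-Indolepropionic acid
FORMULA: C11H11NO2
EXACTMASS: 189.0790
RETENTIONTIME: 5.40
SOURCE: public
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 3
118.0651 100
130.0651 60
143.0730 30

NAME: Serotonin
FORMULA: C10H12N2O
EXACTMASS: 176.0950
RETENTIONTIME: 2.15
SOURCE: public
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 3
115.0542 35
132.0808 100
160.0757 50

NAME: Catechol-O-sulfate
FORMULA: C6H6O5S
EXACTMASS: 189.9936
RETENTIONTIME: 2.80
SOURCE: public
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 2
109.0284 100
80.9652 70

NAME: Carnitine
FORMULA: C7H15NO3
EXACTMASS: 161.1052
RETENTIONTIME: 1.20
SOURCE: in_house
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 3
60.0808 100
85.0284 60
102.0913 45

NAME: Solanidine
FORMULA: C27H43NO
EXACTMASS: 397.3345
RETENTIONTIME: 9.80
SOURCE: public
COMMENT: synthetic demonstration entry (spectrum simulated)
Num Peaks: 2
98.0964 100
380.3312 40
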