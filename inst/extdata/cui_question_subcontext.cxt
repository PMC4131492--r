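B

8
3

Q1
Q2
Q3
Q4
Q5
Q6
Q7
Q8
C0232908
C0025874
C0439531
.XX
XX.
XX.
XXX
.XX
.XX
XXX
.XX
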