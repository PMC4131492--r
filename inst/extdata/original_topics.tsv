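question_id	topics
Q1	Gynecology
Q2	Pregnancy
Q3	Pregnancy
Q4	Pregnancy
Q5	Gynecology
Q6	Infertility
Q7	Women's Health
Q8	Gynecology
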