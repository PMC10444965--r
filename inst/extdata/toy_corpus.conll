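the	O
frequency	O
at	O
which	O
we	O
have	O
found	O
PAX6	O
mutations	O
suggests	O
that	O
lesions	O
in	O
PAX6	O
will	O
account	O
for	O
most	O
cases	O
of	O
aniridia	B-Disease
.	O

we	O
were	O
able	O
to	O
map	O
the	O
human	O
gene	O
to	O
chromosome	O
3q	O
in	O
six	O
alkaptonuria	B-Disease
pedigrees	O
of	O
slovak	O
origin	O
.	O

the	O
patient	O
reported	O
severe	O
myalgias	B-Disease
after	O
treatment	O
.	O

hypertension	B-Disease
was	O
reported	O
to	O
increase	O
intracellular	O
calcium	O
levels	O
.	O
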