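stack	delta_g
AA/UU	-0.93
AU/UA	-1.1
AC/UG	-2.24
AG/UC	-2.08
AG/UU	-1.14
AU/UG	-1.23
UA/AU	-1.33
UU/AA	-0.93
UC/AG	-2.35
UG/AC	-2.11
UG/AU	-1.16
UU/AG	-1.29
CA/GU	-2.11
CU/GA	-2.08
CC/GG	-3.26
CG/GC	-2.36
CG/GU	-1.3
CU/GG	-1.79
GA/CU	-2.35
GU/CA	-2.24
GC/CG	-3.42
GG/CC	-3.26
GG/CU	-1.79
GU/CG	-1.88
GA/UU	-1.29
GU/UA	-1.23
GC/UG	-1.88
GG/UC	-1.79
GG/UU	-0.99
GU/UG	-1.03
UA/GU	-1.16
UU/GA	-1.14
UC/GG	-1.79
UG/GC	-1.3
UG/GU	-0.71
UU/GG	-0.99
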