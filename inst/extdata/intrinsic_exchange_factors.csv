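# Side-chain correction factors (log10) for backbone amide intrinsic
# exchange rates, poly-DL-alanine reference scale.
# Source: Bai, Milne, Mayne & Englander (1993) Proteins 17:75-86, Table 2
# (values as implemented in the SPHERE-style calculators).
# Convention: the intrinsic rate of the amide of residue i multiplies the
# 'self' factors of residue i and the 'prev' factors of residue i-1:
#   log10 k_acid = log10 kA_ref + acid_self(i) + acid_prev(i-1) - pD
#   log10 k_base = log10 kB_ref + base_self(i) + base_prev(i-1) + pD - pK
#   log10 k_water = log10 kW_ref + base_self(i) + base_prev(i-1)
# Charge states are those dominant near neutral pH (Asp/Glu carboxylates;
# His treated with its protonated-form factors, titration not modelled).
# Rows NT2/CT are the charged terminus corrections: NT2 applies (as 'prev')
# to the amide of residue 2; CT applies (as 'self') to the C-terminal amide.
residue,acid_self,acid_prev,base_self,base_prev
ALA,0.00,0.00,0.00,0.00
ARG,-0.59,-0.32,0.08,0.22
ASN,-0.58,-0.13,0.49,0.32
ASP,0.90,0.58,0.10,-0.18
CYS,-0.54,-0.46,0.62,0.55
GLN,-0.47,-0.27,0.06,0.20
GLU,-0.90,0.31,-0.11,-0.15
GLY,-0.22,0.22,0.27,0.17
HIS,-0.80,-0.51,0.80,0.83
ILE,-0.91,-0.59,-0.73,-0.23
LEU,-0.57,-0.13,-0.58,-0.21
LYS,-0.56,-0.29,-0.04,0.12
MET,-0.64,-0.28,-0.01,0.11
PHE,-0.52,-0.43,-0.24,0.06
PRO,0.00,-0.19,0.00,-0.24
SER,-0.44,-0.39,0.37,0.30
THR,-0.79,-0.47,-0.07,0.20
TRP,-0.40,-0.44,-0.41,-0.11
TYR,-0.41,-0.37,-0.27,0.05
VAL,-0.74,-0.30,-0.70,-0.14
NT2,0.00,-1.32,0.00,1.62
CT,0.96,0.00,-1.80,0.00
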