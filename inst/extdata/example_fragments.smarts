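# Example structural fragment list (one SMARTS per line, '#' = comment).
# A small hand-picked set of generic functional groups; for the full MACCS
# 166-key list use maccs_smarts(), which queries RDKit at run time.
c1ccccc1          # benzene ring
[#8]              # any oxygen
[#7]              # any nitrogen
[OX2H]            # hydroxyl
C(=O)[OX2H1]      # carboxylic acid
C(=O)N            # amide
S(=O)(=O)         # sulfonyl
[F,Cl,Br,I]       # halogen
N=N               # azo
C#N               # nitrile
[NX3;H2]          # primary amine
O=C               # carbonyl
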