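# Allele-specific hypotheses: for each variant, the allele hypothesized to
# INCREASE dopamine signalling (the "effect allele" summed in the polygenic
# risk score), expressed relative to the counted allele of the additive
# 0/1/2 coding. orientation = "counted" when the effect allele is the
# counted allele (score adds the code) and "opposite" when it is the other
# allele or the absence of the focal VNTR repeat (score adds 2 - code).
# Note on rs6275: the hypothesis table pairs the G allele's increased DRD2
# expression with DECREASED dopamine signalling (D2 autoreceptor logic);
# the mapping below encodes that hypothesis as stated.
variant_id,gene,kind,counted_allele,effect_allele,orientation,hypothesis
rs265981,DRD1,snp,A,G,opposite,A decreases DRD1 expression
rs6275,DRD2,snp,A,A,counted,G increases DRD2 expression (dopamine down)
rs1800497,DRD2,snp,A,A,counted,A reduces inhibitory D2 receptor number
rs6280,DRD3,snp,T,T,counted,C glycine variant has higher dopamine affinity
rs1800955,DRD4,snp,C,T,opposite,C increases DRD4 expression
DRD4_vntr,DRD4,vntr,7,7,counted,7-repeat lowers receptor affinity for dopamine
DRD5_vntr,DRD5,vntr,148,absence-of-focal,opposite,148 allele decreases DRD5 expression
rs1611115,DBH,snp,C,T,opposite,C raises DBH activity (dopamine converted away)
rs2519152,DBH,snp,T,T,counted,T lowers DBH activity
DAT1_vntr,DAT1,vntr,480,absence-of-focal,opposite,480 allele raises DAT expression and reuptake
rs4680,COMT,snp,A,G,opposite,G degrades dopamine more slowly
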