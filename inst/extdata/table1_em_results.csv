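model,dielectric,reflected_pct,absorbed_pct,b1_per_sqrtW_uT,b1_cov,head_avg_perW,wb_avg_perW,pssar10g_perW,pssar10g_head_perW,head_avg_perB1sq,wb_avg_perB1sq,pssar10g_perB1sq,pssar10g_head_perB1sq
neonateA,adult,13,58,0.61,0.23,0.41,0.17,0.95,0.95,1.12,0.45,2.58,2.58
neonateA,neonatal,11,59,0.53,0.17,0.40,0.16,1.10,0.92,1.39,0.57,3.84,3.21
neonateB,adult,17,47,0.62,0.22,0.32,0.13,0.94,0.94,0.81,0.35,2.41,2.41
neonateB,adult_simplified,17,47,0.61,0.22,0.31,0.13,0.91,0.91,0.83,0.35,2.41,2.41
neonateB,neonatal,16,52,0.53,0.16,0.35,0.15,1.08,1.08,1.21,0.51,3.78,3.78
duke,adult,0.4,88,0.47,0.19,0.15,0.01,0.45,0.45,0.69,0.05,2.05,2.05
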