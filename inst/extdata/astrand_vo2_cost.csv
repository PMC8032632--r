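# Assumed oxygen cost of cycle-ergometer work at 50-60 rev/min used by the
# Astrand-Ryhming nomogram (L/min at a given workload in kpm/min; 1 W is
# taken as 6.12 kpm/min). Values are the standard ladder published with the
# nomogram (300->0.9, 450->1.2, 600->1.5, 750->1.8, 900->2.1, 1200->2.8,
# 1500->3.5), with a 0.30 L/min unloaded-cycling intercept; intermediate
# workloads are linearly interpolated.
workload_kpm,vo2_l_min
0,0.30
300,0.90
450,1.20
600,1.50
750,1.80
900,2.10
1200,2.80
1500,3.50
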