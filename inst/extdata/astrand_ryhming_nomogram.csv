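# Astrand-Ryhming submaximal cycle-ergometer nomogram, parametric form.
# The nomogram relates steady-state pulse rate at a known workload to
# estimated maximal oxygen uptake through a linear pulse-rate/%VO2max
# relation anchored at the mean heart rate at 50% VO2max reported for the
# nomogram population (128 beats/min for men, 138 for women) and a mean
# reference maximal heart rate of 195 beats/min (Astrand & Ryhming, J Appl
# Physiol 7:218-221, 1954). These parameters generate the nomogram line
# used for table lookup; the tabulated validity range of the steady-state
# pulse is 120-170 beats/min and no extrapolation is performed outside it.
sex,hr_at_half_max,hr_max_ref,hr_valid_low,hr_valid_high
male,128,195,120,170
female,138,195,120,170
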