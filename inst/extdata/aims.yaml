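# Tunable knobs of the aims / over- / under-treatment rule engine.
# The band thresholds themselves (primary aim < 20/30/45, minimal aim
# < 45/60, over-treatment margin 5 + (start - 20)/2 with end < 30,
# under-treatment at the 30- and 60-degree thresholds) are fixed in the
# classifiers; see ?classify_aims, ?classify_over_treatment,
# ?classify_under_treatment.
change_delta: 5                        # radiographic measurement error, degrees
under_treatment_any_progression: false # strict reading for 30-40 degree starts
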