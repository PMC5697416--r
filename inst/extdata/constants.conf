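# Fixed internal constants of the closed-loop model (units: mmHg, ml, s).
# Frozen output of the one-time baseline calibration, which tunes the free
# constants so the normal preset reproduces 120/80 mmHg and 5 l/min at
# HR 60; all disease presets reuse these values unchanged.
E_lv_min = 0.039867      # diastolic LV elastance, mmHg/ml
E_la_min = 0.221524      # resting atrial elastance, mmHg/ml
E_la_max = 0.282894      # peak atrial elastance, mmHg/ml
R_mi = 0.01              # open mitral valve resistance, mmHg.s/ml
R_ao = 0.01              # open aortic valve resistance, mmHg.s/ml
R_ven = 0.115502         # venous-return resistance, mmHg.s/ml
C_ven = 171.21           # venous (capacitance-bed) compliance, ml/mmHg
V0_la = 5                # atrial unstressed volume, ml
V0_lv = 10               # ventricular unstressed volume, ml
V0_art = 600             # arterial unstressed volume, ml
V0_ven = 1872.6          # venous unstressed volume, ml
f_peak = 0.218808        # ventricular activation peak, fraction of T
f_end = 0.495060         # end of systole, fraction of T
f_atrial_onset = 0.85    # atrial beat onset, fraction of T
f_atrial_end = 1.0       # atrial beat end, fraction of T
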