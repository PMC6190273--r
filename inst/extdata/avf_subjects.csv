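subject_id,d,D,dos,age,gender,class
S01,1.52,1.63,0.130415,81,male,1
S02,1.09,1.18,0.146725,78,male,1
S03,1.17,1.36,0.259894,87,male,1
S04,0.94,0.99,0.146725,86,male,1
S05,0.78,0.89,0.145607,65,female,1
S06,0.812,0.961,0.34535,81,male,1
S07,0.698,0.797,0.145607,54,male,1
S08,1.45,1.71,0.137399,81,male,1
S09,0.698,0.797,0.267894,81,male,2
S10,0.78,0.89,0.145665,54,male,2
S11,0.78,0.89,0.352678,67,female,2
S12,0.812,0.961,0.268303,87,female,2
S13,0.78,0.89,0.278894,84,female,2
S14,0.87,0.68,0.353638,83,male,2
S15,0.812,0.961,0.268303,86,male,2
S16,0.812,0.961,0.278894,84,male,2
S17,0.94,0.99,0.26383,75,female,3
S18,0.78,0.89,0.489894,86,male,3
S19,0.812,0.961,0.474949,85,male,3
S20,0.812,0.961,0.474940,89,male,3
S21,0.812,0.961,0.659894,83,female,3
S22,0.78,0.75,0.373282,83,male,3
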