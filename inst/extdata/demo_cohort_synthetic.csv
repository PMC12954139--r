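subject_id,sex,age_years,height_m,weight_kg
D001,female,58.8,1.632,47.77
D002,male,20.6,1.787,64.25
D003,female,40.4,1.597,53.05
D004,male,36.6,1.657,66.88
D005,male,27.4,1.701,60.54
D006,female,65.6,1.61,59.14
D007,male,65.4,1.71,68.22
D008,male,40.1,1.645,65.18
D009,female,38.8,1.547,45.43
D010,male,63.2,1.75,75.39
D011,female,51.3,1.588,63.2
D012,female,69.6,1.654,54.85
D013,female,40.1,1.586,54.9
D014,female,21.8,1.557,46.26
D015,female,70.3,1.581,49.42
D016,male,29.5,1.718,55.48
D017,female,63.3,1.558,52.75
D018,male,67.6,1.655,60.11
D019,male,46.9,1.762,97.48
D020,female,57.9,1.583,65.98
D021,male,56.1,1.643,78.5
D022,male,55.3,1.692,73.43
D023,female,27.8,1.556,66.41
D024,male,51.6,1.71,76.02
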