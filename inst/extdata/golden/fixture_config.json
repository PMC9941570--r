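{"cohort_csv":"cohort.csv","output_dir":"scratch/golden_build","synthetic":{"n_children":150,"m_rois":10,"age_range":[0.17000000000000001,10],"visits_pmf":[0.55054151624548742,0.23646209386281589,0.10108303249097472,0.061371841155234655,0.030685920577617327,0.016245487364620937,0.0018050541516245488,0.0018050541516245488],"p_male":0.5577617328519856,"p_high_mated":0.62,"elc_mean":100,"elc_sd":15,"block_split":[1,2,3],"rho":{"within_base":0.34999999999999998,"within_slope":0.29999999999999999,"mated_gain":0.10000000000000001,"elc_gain":-0.10000000000000001,"between_base":0.10000000000000001,"between_slope":0.10000000000000001,"boost_group":null,"boost_after":5,"boost_amount":0},"growth":{"c":0.69999999999999996,"k":0.69999999999999996},"adult_volumes":[4.9999999999999991,6.4577483250744185,8.3405026860002938,10.772173450159421,13.912797011035622,17.96906831902313,23.2079441680639,29.974212515947052,38.713184134056341,49.999999999999993],"cv":0.12,"child_effect_sd":0,"seed":424242},"mode":"groups","ages":[1,2,3,4,5,6,7,8,9],"thresholds":[0.59999999999999998,0.65000000000000002,0.69999999999999996,0.75,0.80000000000000004,0.84999999999999998,0.90000000000000002],"kernel":"gaussian","bandwidth":null,"measures":["modularity","global_efficiency"],"length_rule":"weight","Q":50,"unit":"visit","scores":[80,100,120],"restarts":5,"seed":424242}
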