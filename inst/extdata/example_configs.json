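{"starved":{"name":"starved","egf_ngml":0,"ins_ugml":0,"trail_ngml":0,"meki_um":0,"akti_um":0,"etop_um":0,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"gf":{"name":"gf","egf_ngml":20,"ins_ugml":10,"trail_ngml":0,"meki_um":0,"akti_um":0,"etop_um":0,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"egf":{"name":"egf","egf_ngml":20,"ins_ugml":0,"trail_ngml":0,"meki_um":0,"akti_um":0,"etop_um":0,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"insulin":{"name":"insulin","egf_ngml":0,"ins_ugml":10,"trail_ngml":0,"meki_um":0,"akti_um":0,"etop_um":0,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"gf_meki":{"name":"gf_meki","egf_ngml":20,"ins_ugml":10,"trail_ngml":0,"meki_um":10,"akti_um":0,"etop_um":0,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"gf_akti":{"name":"gf_akti","egf_ngml":20,"ins_ugml":10,"trail_ngml":0,"meki_um":0,"akti_um":10,"etop_um":0,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"gf_meki_akti":{"name":"gf_meki_akti","egf_ngml":20,"ins_ugml":10,"trail_ngml":0,"meki_um":10,"akti_um":10,"etop_um":0,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"etop":{"name":"etop","egf_ngml":0,"ins_ugml":0,"trail_ngml":0,"meki_um":0,"akti_um":0,"etop_um":100,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"gf_etop":{"name":"gf_etop","egf_ngml":20,"ins_ugml":10,"trail_ngml":0,"meki_um":0,"akti_um":0,"etop_um":100,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"meki":{"name":"meki","egf_ngml":0,"ins_ugml":0,"trail_ngml":0,"meki_um":10,"akti_um":0,"etop_um":0,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"akti":{"name":"akti","egf_ngml":0,"ins_ugml":0,"trail_ngml":0,"meki_um":0,"akti_um":10,"etop_um":0,"duration_h":72,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[24,48,72]},"trail_2":{"name":"trail_2","egf_ngml":0,"ins_ugml":0,"trail_ngml":2,"meki_um":0,"akti_um":0,"etop_um":0,"duration_h":24,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[5,24]},"trail_10":{"name":"trail_10","egf_ngml":0,"ins_ugml":0,"trail_ngml":10,"meki_um":0,"akti_um":0,"etop_um":0,"duration_h":24,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[5,24]},"trail_30":{"name":"trail_30","egf_ngml":0,"ins_ugml":0,"trail_ngml":30,"meki_um":0,"akti_um":0,"etop_um":0,"duration_h":24,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[5,24]},"trail_100":{"name":"trail_100","egf_ngml":0,"ins_ugml":0,"trail_ngml":100,"meki_um":0,"akti_um":0,"etop_um":0,"duration_h":24,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[5,24]},"trail_300":{"name":"trail_300","egf_ngml":0,"ins_ugml":0,"trail_ngml":300,"meki_um":0,"akti_um":0,"etop_um":0,"duration_h":24,"n_cells":100,"base_seed":1,"save_stride_min":6,"readout_times":[5,24]}}
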