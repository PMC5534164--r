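species,t2_acc_initial,t2_ext_initial,t2_acc_low_accuracy,t2_ext_low_accuracy,t2_acc_duplicates,t2_ext_duplicates,t2_acc_quality_le,t2_ext_quality_le,t2_acc_quality_gt,t2_ext_quality_gt,t4_n_external,t4_spatial_gaps,t4_priority_gaps,t4_pct_priority,t5_n_categories,t5_n_represented,t5_pct_represented,t5_spatial_gap_categories,t5_priority_gap_categories,t5_pct_improvement,t6_n_arid,t6_n_selected,t8_pc_categories,t8_pct_improvement
Ae. biuncialis,6,30,0,13,0,1,2,1,4,15,15,15,12,80,26,2,8,9,7,27,10,2,2,8
Ae. geniculata,144,4850,0,1292,20,1879,5,317,119,1362,1362,1359,140,10,27,13,48,26,12,44,103,21,3,11
Ae. neglecta,33,870,0,372,1,71,3,73,29,354,354,317,133,38,27,7,26,26,19,70,76,15,3,11
Ae. triuncialis,191,1674,0,580,12,221,5,148,174,725,725,722,73,10,27,11,41,22,11,41,26,5,2,7
Ae. ventricosa,26,363,0,99,2,63,5,43,19,158,158,158,35,22,27,6,22,18,12,44,8,2,2,7
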