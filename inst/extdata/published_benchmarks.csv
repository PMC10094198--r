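table,class,auc,accuracy,precision,recall,f1
ptbxl_full,NORM,0.924,0.905,0.877,0.849,0.863
ptbxl_full,MI,0.898,0.912,0.814,0.734,0.772
ptbxl_full,STTC,0.926,0.869,0.834,0.813,0.823
ptbxl_full,CD,0.946,0.868,0.867,0.872,0.869
ptbxl_full,HYP,0.933,0.883,0.852,0.819,0.835
cpsc_full,SNR,0.973,0.948,0.824,0.824,0.824
cpsc_full,AF,0.981,0.962,0.885,0.968,0.925
cpsc_full,IAVB,0.981,0.977,0.923,0.845,0.882
cpsc_full,LBBB,0.999,0.996,0.957,0.917,0.937
cpsc_full,RBBB,0.994,0.965,0.944,0.934,0.939
cpsc_full,PAC,0.961,0.951,0.712,0.758,0.734
cpsc_full,PVC,0.962,0.959,0.885,0.676,0.767
cpsc_full,STD,0.984,0.962,0.868,0.805,0.835
cpsc_full,STE,0.960,0.977,0.667,0.545,0.600
cpsc_random_aux,SNR,0.974,0.952,0.848,0.824,0.836
cpsc_random_aux,AF,0.980,0.965,0.866,0.915,0.890
cpsc_random_aux,IAVB,0.983,0.975,0.897,0.859,0.878
cpsc_random_aux,LBBB,0.999,0.996,0.957,0.917,0.937
cpsc_random_aux,RBBB,0.993,0.969,0.936,0.960,0.948
cpsc_random_aux,PAC,0.952,0.948,0.671,0.823,0.739
cpsc_random_aux,PVC,0.969,0.962,0.809,0.765,0.786
cpsc_random_aux,STD,0.980,0.956,0.777,0.890,0.830
cpsc_random_aux,STE,0.956,0.968,0.500,0.318,0.389
ptbxl_random_aux,NORM,0.917,0.889,0.845,0.839,0.842
ptbxl_random_aux,MI,0.883,0.907,0.807,0.699,0.749
ptbxl_random_aux,STTC,0.923,0.863,0.840,0.781,0.809
ptbxl_random_aux,CD,0.935,0.859,0.861,0.865,0.863
ptbxl_random_aux,HYP,0.925,0.879,0.851,0.806,0.828
ptbxl_no_cot,NORM,0.908,0.893,0.870,0.815,0.842
ptbxl_no_cot,MI,0.881,0.904,0.782,0.735,0.758
ptbxl_no_cot,STTC,0.917,0.865,0.824,0.816,0.820
ptbxl_no_cot,CD,0.935,0.859,0.858,0.861,0.859
ptbxl_no_cot,HYP,0.911,0.869,0.827,0.808,0.817
cpsc_no_cot,SNR,0.973,0.946,0.835,0.794,0.814
cpsc_no_cot,AF,0.979,0.958,0.860,0.868,0.864
cpsc_no_cot,IAVB,0.979,0.971,0.905,0.803,0.851
cpsc_no_cot,LBBB,0.998,0.988,0.750,0.900,0.818
cpsc_no_cot,RBBB,0.992,0.964,0.918,0.960,0.939
cpsc_no_cot,PAC,0.956,0.948,0.741,0.645,0.690
cpsc_no_cot,PVC,0.960,0.961,0.918,0.662,0.769
cpsc_no_cot,STD,0.983,0.951,0.809,0.878,0.842
cpsc_no_cot,STE,0.941,0.957,0.444,0.182,0.258
ptbxl_no_bigru,NORM,0.904,0.892,0.855,0.832,0.843
ptbxl_no_bigru,MI,0.877,0.899,0.766,0.749,0.757
ptbxl_no_bigru,STTC,0.914,0.869,0.835,0.810,0.822
ptbxl_no_bigru,CD,0.931,0.861,0.859,0.860,0.859
ptbxl_no_bigru,HYP,0.911,0.874,0.850,0.789,0.818
cpsc_no_bigru,SNR,0.964,0.939,0.768,0.843,0.804
cpsc_no_bigru,AF,0.989,0.965,0.918,0.849,0.882
cpsc_no_bigru,IAVB,0.982,0.975,0.922,0.831,0.874
cpsc_no_bigru,LBBB,0.998,0.988,0.750,0.900,0.818
cpsc_no_bigru,RBBB,0.991,0.955,0.935,0.944,0.939
cpsc_no_bigru,PAC,0.963,0.948,0.716,0.774,0.744
cpsc_no_bigru,PVC,0.952,0.952,0.893,0.735,0.806
cpsc_no_bigru,STD,0.982,0.965,0.890,0.793,0.839
cpsc_no_bigru,STE,0.961,0.964,0.571,0.545,0.558
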