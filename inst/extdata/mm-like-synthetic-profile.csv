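z_star,Aa_m2,gamma_m
0.18,0.000398,0.764
0.196,0.00040780008088627,0.78281221557063
0.212,0.000436959013029058,0.838785643101005
0.228,0.000484758806746059,0.930542031040174
0.244,0.000550022472477542,1.05582203259508
0.26,0.000631143002175508,1.21154083834696
0.276,0.000726122939175191,1.3938641344971
0.292,0.000832623562207321,1.59830251639797
0.308,0.000948022472477542,1.81982203259508
0.324,0.00106947816582798,2.05296813741853
0.34,0.001194,2.292
0.356,0.00131852183417202,2.53103186258147
0.372,0.00143997752752246,2.76417796740492
0.388,0.00155537643779268,2.98569748360203
0.404,0.00166187706082481,3.1901358655029
0.42,0.00175685699782449,3.37245916165304
0.436,0.00183797752752246,3.52817796740492
0.452,0.00190324119325394,3.65345796895983
0.468,0.00195104098697094,3.74521435689899
0.484,0.00198019991911373,3.80118778442937
0.5,0.00199,3.82
0.516,0.00198019991911373,3.80118778442937
0.532,0.00195104098697094,3.74521435689899
0.548,0.00190324119325394,3.65345796895983
0.564,0.00183797752752246,3.52817796740492
0.58,0.00175685699782449,3.37245916165305
0.596,0.00166187706082481,3.1901358655029
0.612,0.00155537643779268,2.98569748360203
0.628,0.00143997752752246,2.76417796740492
0.644,0.00131852183417202,2.53103186258147
0.66,0.001194,2.292
0.676,0.00106947816582798,2.05296813741853
0.692,0.000948022472477541,1.81982203259508
0.708,0.00083262356220732,1.59830251639797
0.724,0.000726122939175191,1.3938641344971
0.74,0.000631143002175507,1.21154083834695
0.756,0.000550022472477542,1.05582203259508
0.772,0.000484758806746059,0.930542031040174
0.788,0.000436959013029058,0.838785643101005
0.804,0.00040780008088627,0.78281221557063
0.82,0.000398,0.764
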