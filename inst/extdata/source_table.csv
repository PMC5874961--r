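rs_mm,sigma_x,sigma_y,sigma_tx,sigma_ty,L_x,L_y
2,4.62,4.75,5.95,5.76,989.40,922.50
32,5.61,5.48,17.08,17.01,491.00,479.40
64,5.25,5.19,25.82,25.78,599.70,595.01
96,6.33,6.23,38.37,38.34,501.38,499.10
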