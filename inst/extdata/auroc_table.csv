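experiment,model,finding,auroc,margin
internal,reference,cardiomegaly,0.814,0.0108
internal,reference,edema,0.8929,0.012
internal,reference,consolidation,0.8549,0.0177
internal,reference,atelectasis,0.807,0.0117
internal,reference,pneumothorax,0.8669,0.0226
internal,reference,pleural_effusion,0.91,0.0072
internal,orig,cardiomegaly,0.7704,0.0217
internal,orig,edema,0.7863,0.0144
internal,orig,consolidation,0.7248,0.0299
internal,orig,atelectasis,0.6383,0.0187
internal,orig,pneumothorax,0.7587,0.03
internal,orig,pleural_effusion,0.8686,0.0105
internal,reca,cardiomegaly,0.7986,0.0112
internal,reca,edema,0.8775,0.0122
internal,reca,consolidation,0.8097,0.0217
internal,reca,atelectasis,0.7868,0.0123
internal,reca,pneumothorax,0.8408,0.023
internal,reca,pleural_effusion,0.8957,0.0077
external,reference,cardiomegaly,0.8173,0.0193
external,reference,edema,0.7796,0.0144
external,reference,consolidation,0.7564,0.0302
external,reference,atelectasis,0.632,0.0194
external,reference,pneumothorax,0.7266,0.0343
external,reference,pleural_effusion,0.8891,0.0096
external,orig,cardiomegaly,0.7067,0.0236
external,orig,edema,0.6811,0.0168
external,orig,consolidation,0.675,0.0329
external,orig,atelectasis,0.6115,0.0204
external,orig,pneumothorax,0.5822,0.038
external,orig,pleural_effusion,0.7781,0.0133
external,trns,cardiomegaly,0.7385,0.0229
external,trns,edema,0.7187,0.016
external,trns,consolidation,0.7368,0.0292
external,trns,atelectasis,0.6235,0.0187
external,trns,pneumothorax,0.6367,0.0408
external,trns,pleural_effusion,0.8318,0.0121
external,phot,cardiomegaly,0.6108,0.0247
external,phot,edema,0.6226,0.0182
external,phot,consolidation,0.6112,0.0369
external,phot,atelectasis,0.5329,0.0205
external,phot,pneumothorax,0.5216,0.0316
external,phot,pleural_effusion,0.6391,0.0165
external,reca,cardiomegaly,0.7971,0.0193
external,reca,edema,0.7641,0.0155
external,reca,consolidation,0.7425,0.0288
external,reca,atelectasis,0.6221,0.0193
external,reca,pneumothorax,0.7119,0.0341
external,reca,pleural_effusion,0.857,0.0111
enduser,orig,cardiomegaly,0.7414,0.0224
enduser,orig,edema,0.6899,0.0161
enduser,orig,consolidation,0.6957,0.0355
enduser,orig,atelectasis,0.6108,0.0193
enduser,orig,pneumothorax,0.6737,0.0376
enduser,orig,pleural_effusion,0.7914,0.0136
enduser,trns,cardiomegaly,0.7839,0.0206
enduser,trns,edema,0.7397,0.0158
enduser,trns,consolidation,0.7247,0.0349
enduser,trns,atelectasis,0.6028,0.0193
enduser,trns,pneumothorax,0.648,0.0399
enduser,trns,pleural_effusion,0.8487,0.0115
enduser,phot,cardiomegaly,0.5792,0.0255
enduser,phot,edema,0.6617,0.0172
enduser,phot,consolidation,0.6024,0.0363
enduser,phot,atelectasis,0.5818,0.0211
enduser,phot,pneumothorax,0.576,0.0361
enduser,phot,pleural_effusion,0.6759,0.0159
enduser,reca,cardiomegaly,0.8081,0.0206
enduser,reca,edema,0.769,0.015
enduser,reca,consolidation,0.7295,0.0317
enduser,reca,atelectasis,0.6136,0.0187
enduser,reca,pneumothorax,0.7371,0.0323
enduser,reca,pleural_effusion,0.8645,0.0109
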