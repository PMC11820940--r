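dataset,model,method,metric,value
Across_Data,RO,O,f1,0.5276
Across_Data,BO,O,f1,0.4813
Across_Data,RC,O,f1,0.4485
Across_Data,B,O,f1,0.3706
Across_Data,R,O,f1,0.3279
Across_Data,RO,S,f1,0.5097
Across_Data,BO,S,f1,0.4676
Across_Data,RC,S,f1,0.4533
Across_Data,R,S,f1,0.3297
Across_Data,RO,O,kappa,0.3289
Across_Data,RC,O,kappa,0.3164
Across_Data,BO,O,kappa,0.2415
Across_Data,B,O,kappa,0.2393
Across_Data,R,O,kappa,0.2161
Across_Data,BO,S,kappa,0.2008
Across_Data,RO,S,kappa,0.2809
Across_Data,BO,O,sensitivity,0.7224
Across_Data,RO,O,sensitivity,0.7117
Across_Data,R,O,sensitivity,0.2031
Across_Data,BO,S,sensitivity,0.8182
Across_Data,RO,S,sensitivity,0.7983
Across_Data,R,O,specificity,0.9718
Across_Data,B,O,specificity,0.9199
Across_Data,RC,O,specificity,0.9044
Across_Data,RO,O,specificity,0.6944
Across_Data,BO,O,specificity,0.5858
Across_Data,BO,S,specificity,0.4848
Across_Data,RO,S,specificity,0.5915
Maize_1,RO,O,f1,0.5126
Maize_1,BO,O,f1,0.4813
Maize_1,B,O,f1,0.3638
Maize_1,R,O,f1,0.2895
Maize_1,BO,S,f1,0.4739
Maize_1,RO,S,f1,0.5056
Maize_1,RO,O,kappa,0.3004
Maize_1,RC,O,kappa,0.2914
Maize_1,BO,O,kappa,0.2462
Maize_1,R,O,kappa,0.1734
Maize_1,BO,S,kappa,0.2048
Maize_1,RO,S,kappa,0.2715
Maize_1,RO,O,sensitivity,0.6936
Maize_1,BO,O,sensitivity,0.6784
Maize_1,B,O,sensitivity,0.2982
Maize_1,R,O,sensitivity,0.1586
Maize_1,BO,S,sensitivity,0.8091
Maize_1,RO,S,sensitivity,0.7673
Maize_1,R,O,specificity,0.9786
Maize_1,B,O,specificity,0.9036
Maize_1,RC,O,specificity,0.9017
Maize_1,RO,O,specificity,0.6797
Maize_1,BO,O,specificity,0.6340
Maize_1,BO,S,specificity,0.4939
Maize_1,RO,S,specificity,0.6016
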