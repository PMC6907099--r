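objective,case,tp,fp,fn,tn,accuracy,specificity,sensitivity,topology,activations,moga_accuracy,n_features
1,1,59.75,5.35,3.89,31.02,0.9076,0.8530,0.9389,186/15/2,logsig/logsig/softmax,0.9076,41
1,2,60.36,3.75,3.89,32.62,0.9298,0.8970,0.9486,44/10/2,logsig/logsig/softmax,0.9298,43
1,3,61.67,2.09,1.96,34.27,0.9595,0.9425,0.9691,232/82/7/2,logsig/logsig/logsig/softmax,0.9595,43
1,4,61.40,3.98,2.24,32.38,0.9378,0.8905,0.9649,22/25/2,logsig/logsig/softmax,0.9378,6
1,5,60.35,5.13,2.24,31.24,0.9158,0.8590,0.9483,46/12/2,logsig/logsig/softmax,0.9158,6
1,6,62.11,1.62,1.53,34.75,0.9685,0.9555,0.9760,45/114/21/2,satlins/tansig/logsig/softmax,0.9685,7
2,1,39.51,2.31,3.34,54.83,0.9434,0.9595,0.9220,59/65/2/2,logsig/logsig/logsig/softmax,0.9434,41
2,2,37.43,7.31,5.43,49.83,0.8726,0.8720,0.8733,138/18/1/2,logsig/logsig/logsig/softmax,0.8726,43
2,3,39.51,4.80,3.34,52.34,0.9186,0.9196,0.9220,65/36/7/2,logsig/logsig/logsig/softmax,0.9186,43
2,4,41.31,2.46,1.54,54.69,0.9600,0.9570,0.9640,23/2,logsig/softmax,0.9600,6
2,5,36.51,6.94,6.34,50.20,0.8671,0.8785,0.8520,67/24/2,logsig/logsig/softmax,0.8671,5
2,6,39.29,4.77,3.57,52.37,0.9166,0.9165,0.9167,17/2,tansig/softmax,0.9166,5
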