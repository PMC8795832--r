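resolution,cost,mean,sd,n,margin,lower,upper
8x8,UIQI,25.79,0.92,20,0.430568,25.36,26.22
8x8,RMSE,62.59,4.32,20,2.021799,60.57,64.61
8x8,SSIM,29.35,2.11,20,0.987499,28.36,30.34
8x8,MAE,61.13,7.39,20,3.458587,57.67,64.59
8x8,RSE,29.66,2.15,20,1.006219,28.65,30.67
8x8,RAE,34.88,1.83,20,0.856457,34.02,35.74
8x8,RMSLE,64.33,1.98,20,0.926658,63.40,65.26
16x16,UIQI,19.01,0.82,20,0.383767,18.63,19.39
16x16,RMSE,68.11,3.88,20,1.815875,66.29,69.93
16x16,SSIM,21.88,0.89,20,0.416528,21.46,22.30
16x16,MAE,65.71,3.13,20,1.464868,64.25,67.17
16x16,RSE,21.56,0.97,20,0.453969,21.11,22.01
16x16,RAE,22.53,0.71,20,0.332286,22.20,22.86
16x16,RMSLE,63.41,1.87,20,0.875177,62.53,64.29
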