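{
  "name": "paper_sub",
  "description": "Published subregional (habitat) radiomics score: LASSO logistic coefficients on 7 per-habitat features, interpreted as a linear combination.",
  "intercept": 49.263094558148,
  "coefficients": {
    "Sub1_wavelet.LLH_glszm_SmallAreaHighGrayLevelEmphasis": 0.49585946384375,
    "Sub1_log.sigma.5.0.mm.3D_glcm_Correlation": -3.11826715000125,
    "Sub3_log.sigma.1.0.mm.3D_firstorder_Kurtosis": 0.0477379368324887,
    "Sub2_wavelet.LHH_glrlm_GrayLevelNonUniformityNormalized": -99.5853551879633,
    "Sub3_wavelet.LLL_gldm_LargeDependenceLowGrayLevelEmphasis": 0.00297377200986883,
    "Sub3_wavelet.LHH_glszm_LargeAreaLowGrayLevelEmphasis": 1.21232489590441e-8,
    "Sub3_log.sigma.5.0.mm.3D_glcm_ClusterProminence": -1.23756693776612
  }
}
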