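{
  "name": "paper_voi",
  "description": "Published whole-tumor (VOI) radiomics score: LASSO logistic coefficients on 6 whole-tumor features.",
  "intercept": -1314.76350183194,
  "coefficients": {
    "original_firstorder_InterquartileRange": -0.049373886121726,
    "log.sigma.2.0.mm.3D_glrlm_ShortRunLowGrayLevelEmphasis": -3.3462260807435,
    "log.sigma.5.0.mm.3D_glszm_SizeZoneNonUniformityNormalized": -2.45489742195494,
    "log.sigma.4.0.mm.3D_glcm_Idn": 37.5565903019046,
    "wavelet.LHH_glrlm_GrayLevelVariance": 5112.07298466082,
    "wavelet.HLH_glszm_SmallAreaHighGrayLevelEmphasis": 0.415506640475669
  }
}
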