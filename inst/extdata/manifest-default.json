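{
  "version": "1.0",
  "total_per_region": 1218,
  "filters": [
    "original",
    "log.sigma.1.0.mm.3D",
    "log.sigma.2.0.mm.3D",
    "log.sigma.3.0.mm.3D",
    "log.sigma.4.0.mm.3D",
    "log.sigma.5.0.mm.3D",
    "wavelet.LLL",
    "wavelet.LLH",
    "wavelet.LHL",
    "wavelet.LHH",
    "wavelet.HLL",
    "wavelet.HLH",
    "wavelet.HHL",
    "wavelet.HHH"
  ],
  "families": {
    "firstorder": [
      "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
      "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
    ],
    "glcm": [
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MaximumProbability", "SumEntropy", "SumSquares"
    ],
    "glrlm": [
      "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"
    ],
    "glszm": [
      "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"
    ],
    "gldm": [
      "SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceEntropy", "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis"
    ],
    "ngtdm": ["Coarseness", "Contrast", "Busyness", "Complexity", "Strength"]
  },
  "shape": [
    "VoxelCount", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
    "Sphericity", "Compactness1", "Compactness2", "SphericalDisproportion",
    "Maximum3DDiameter", "MajorAxisLength", "MinorAxisLength",
    "LeastAxisLength", "Elongation", "Flatness"
  ],
  "disc_original": { "method": "width", "value": 25 },
  "disc_filtered": { "method": "count", "value": 32 }
}
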