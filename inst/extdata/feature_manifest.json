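[
  {
    "family": "shape",
    "name": "MeshVolume"
  },
  {
    "family": "shape",
    "name": "VoxelVolume"
  },
  {
    "family": "shape",
    "name": "SurfaceArea"
  },
  {
    "family": "shape",
    "name": "SurfaceVolumeRatio"
  },
  {
    "family": "shape",
    "name": "Sphericity"
  },
  {
    "family": "shape",
    "name": "Maximum3DDiameter"
  },
  {
    "family": "shape",
    "name": "Maximum2DDiameterSlice"
  },
  {
    "family": "shape",
    "name": "Maximum2DDiameterColumn"
  },
  {
    "family": "shape",
    "name": "Maximum2DDiameterRow"
  },
  {
    "family": "shape",
    "name": "MajorAxisLength"
  },
  {
    "family": "shape",
    "name": "MinorAxisLength"
  },
  {
    "family": "shape",
    "name": "LeastAxisLength"
  },
  {
    "family": "shape",
    "name": "Elongation"
  },
  {
    "family": "shape",
    "name": "Flatness"
  },
  {
    "family": "firstorder",
    "name": "Energy"
  },
  {
    "family": "firstorder",
    "name": "TotalEnergy"
  },
  {
    "family": "firstorder",
    "name": "Entropy"
  },
  {
    "family": "firstorder",
    "name": "Minimum"
  },
  {
    "family": "firstorder",
    "name": "10Percentile"
  },
  {
    "family": "firstorder",
    "name": "90Percentile"
  },
  {
    "family": "firstorder",
    "name": "Maximum"
  },
  {
    "family": "firstorder",
    "name": "Mean"
  },
  {
    "family": "firstorder",
    "name": "Median"
  },
  {
    "family": "firstorder",
    "name": "InterquartileRange"
  },
  {
    "family": "firstorder",
    "name": "Range"
  },
  {
    "family": "firstorder",
    "name": "MeanAbsoluteDeviation"
  },
  {
    "family": "firstorder",
    "name": "RobustMeanAbsoluteDeviation"
  },
  {
    "family": "firstorder",
    "name": "RootMeanSquared"
  },
  {
    "family": "firstorder",
    "name": "Skewness"
  },
  {
    "family": "firstorder",
    "name": "Kurtosis"
  },
  {
    "family": "firstorder",
    "name": "Variance"
  },
  {
    "family": "firstorder",
    "name": "Uniformity"
  },
  {
    "family": "glcm",
    "name": "Autocorrelation"
  },
  {
    "family": "glcm",
    "name": "ClusterProminence"
  },
  {
    "family": "glcm",
    "name": "ClusterShade"
  },
  {
    "family": "glcm",
    "name": "ClusterTendency"
  },
  {
    "family": "glcm",
    "name": "Contrast"
  },
  {
    "family": "glcm",
    "name": "Correlation"
  },
  {
    "family": "glcm",
    "name": "DifferenceAverage"
  },
  {
    "family": "glcm",
    "name": "DifferenceEntropy"
  },
  {
    "family": "glcm",
    "name": "DifferenceVariance"
  },
  {
    "family": "glcm",
    "name": "Id"
  },
  {
    "family": "glcm",
    "name": "Idm"
  },
  {
    "family": "glcm",
    "name": "Idmn"
  },
  {
    "family": "glcm",
    "name": "Idn"
  },
  {
    "family": "glcm",
    "name": "Imc1"
  },
  {
    "family": "glcm",
    "name": "Imc2"
  },
  {
    "family": "glcm",
    "name": "InverseVariance"
  },
  {
    "family": "glcm",
    "name": "JointAverage"
  },
  {
    "family": "glcm",
    "name": "JointEnergy"
  },
  {
    "family": "glcm",
    "name": "JointEntropy"
  },
  {
    "family": "glcm",
    "name": "MaximumProbability"
  },
  {
    "family": "glcm",
    "name": "SumEntropy"
  },
  {
    "family": "glcm",
    "name": "SumSquares"
  },
  {
    "family": "glrlm",
    "name": "ShortRunEmphasis"
  },
  {
    "family": "glrlm",
    "name": "LongRunEmphasis"
  },
  {
    "family": "glrlm",
    "name": "GrayLevelNonUniformity"
  },
  {
    "family": "glrlm",
    "name": "GrayLevelNonUniformityNormalized"
  },
  {
    "family": "glrlm",
    "name": "RunLengthNonUniformity"
  },
  {
    "family": "glrlm",
    "name": "RunLengthNonUniformityNormalized"
  },
  {
    "family": "glrlm",
    "name": "RunPercentage"
  },
  {
    "family": "glrlm",
    "name": "GrayLevelVariance"
  },
  {
    "family": "glrlm",
    "name": "RunVariance"
  },
  {
    "family": "glrlm",
    "name": "RunEntropy"
  },
  {
    "family": "glrlm",
    "name": "LowGrayLevelRunEmphasis"
  },
  {
    "family": "glrlm",
    "name": "HighGrayLevelRunEmphasis"
  },
  {
    "family": "glrlm",
    "name": "ShortRunLowGrayLevelEmphasis"
  },
  {
    "family": "glrlm",
    "name": "ShortRunHighGrayLevelEmphasis"
  },
  {
    "family": "glrlm",
    "name": "LongRunLowGrayLevelEmphasis"
  },
  {
    "family": "glrlm",
    "name": "LongRunHighGrayLevelEmphasis"
  },
  {
    "family": "glszm",
    "name": "SmallAreaEmphasis"
  },
  {
    "family": "glszm",
    "name": "LargeAreaEmphasis"
  },
  {
    "family": "glszm",
    "name": "GrayLevelNonUniformity"
  },
  {
    "family": "glszm",
    "name": "GrayLevelNonUniformityNormalized"
  },
  {
    "family": "glszm",
    "name": "SizeZoneNonUniformity"
  },
  {
    "family": "glszm",
    "name": "SizeZoneNonUniformityNormalized"
  },
  {
    "family": "glszm",
    "name": "ZonePercentage"
  },
  {
    "family": "glszm",
    "name": "GrayLevelVariance"
  },
  {
    "family": "glszm",
    "name": "ZoneVariance"
  },
  {
    "family": "glszm",
    "name": "ZoneEntropy"
  },
  {
    "family": "glszm",
    "name": "LowGrayLevelZoneEmphasis"
  },
  {
    "family": "glszm",
    "name": "HighGrayLevelZoneEmphasis"
  },
  {
    "family": "glszm",
    "name": "SmallAreaLowGrayLevelEmphasis"
  },
  {
    "family": "glszm",
    "name": "SmallAreaHighGrayLevelEmphasis"
  },
  {
    "family": "glszm",
    "name": "LargeAreaLowGrayLevelEmphasis"
  },
  {
    "family": "glszm",
    "name": "LargeAreaHighGrayLevelEmphasis"
  },
  {
    "family": "gldm",
    "name": "SmallDependenceEmphasis"
  },
  {
    "family": "gldm",
    "name": "LargeDependenceEmphasis"
  },
  {
    "family": "gldm",
    "name": "GrayLevelNonUniformity"
  },
  {
    "family": "gldm",
    "name": "DependenceNonUniformity"
  },
  {
    "family": "gldm",
    "name": "DependenceNonUniformityNormalized"
  },
  {
    "family": "gldm",
    "name": "GrayLevelVariance"
  },
  {
    "family": "gldm",
    "name": "DependenceVariance"
  },
  {
    "family": "gldm",
    "name": "DependenceEntropy"
  },
  {
    "family": "gldm",
    "name": "LowGrayLevelEmphasis"
  },
  {
    "family": "gldm",
    "name": "HighGrayLevelEmphasis"
  },
  {
    "family": "gldm",
    "name": "SmallDependenceLowGrayLevelEmphasis"
  },
  {
    "family": "gldm",
    "name": "SmallDependenceHighGrayLevelEmphasis"
  },
  {
    "family": "gldm",
    "name": "LargeDependenceLowGrayLevelEmphasis"
  },
  {
    "family": "gldm",
    "name": "LargeDependenceHighGrayLevelEmphasis"
  },
  {
    "family": "ngtdm",
    "name": "Coarseness"
  },
  {
    "family": "ngtdm",
    "name": "Contrast"
  },
  {
    "family": "ngtdm",
    "name": "Busyness"
  },
  {
    "family": "ngtdm",
    "name": "Complexity"
  },
  {
    "family": "ngtdm",
    "name": "Strength"
  }
]
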