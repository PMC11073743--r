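{
  "factors": ["TJC28", "SJC28", "STAGE", "DrVAS", "PtVAS", "ESR1h", "RF"],
  "theta": [-0.4259, -0.194, -0.2995, -0.0313, 0.7974, -0.0784, 0.6501],
  "w": [
    [0, 0.1922, 0.0028, 0.5739, 0.2281, -0.0108, 0.0189],
    [0.1922, 0, 0.2048, 0.558, 0.0284, 0.1376, -0.0332],
    [0.0028, 0.2048, 0, 0.1392, 0.1422, 0.0141, 0.1811],
    [0.5739, 0.558, 0.1392, 0, 0.2834, 0.1383, 0.0793],
    [0.2281, 0.0284, 0.1422, 0.2834, 0, 0.085, -0.0103],
    [-0.0108, 0.1376, 0.0141, 0.1383, 0.085, 0, 0.2284],
    [0.0189, -0.0332, 0.1811, 0.0793, -0.0103, 0.2284, 0]
  ]
}
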