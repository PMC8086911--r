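{
  "channels": {
    "red": 1100000000,
    "green": 900000000,
    "blue": 1300000000
  },
  "black_level": 400,
  "white_level": 16200,
  "iso_gain": {
    "100": 1,
    "200": 2,
    "400": 4,
    "800": 8
  },
  "aperture_gain": {
    "3.5": 1,
    "8": 0.19140625,
    "22": 0.0253099173553719
  },
  "vignetting": {
    "3.5": [1, 0.996296296296296, 0.985185185185185, 0.966666666666667, 0.940740740740741, 0.907407407407407, 0.866666666666667, 0.818518518518519, 0.762962962962963, 0.7],
    "8": [1, 0.997530864197531, 0.990123456790123, 0.977777777777778, 0.960493827160494, 0.938271604938272, 0.911111111111111, 0.879012345679012, 0.841975308641975, 0.8],
    "22": [1, 0.998765432098765, 0.995061728395062, 0.988888888888889, 0.980246913580247, 0.969135802469136, 0.955555555555556, 0.939506172839506, 0.920987654320988, 0.9]
  },
  "projection": {
    "model": "equisolid",
    "center_xy": [250.5, 250.5],
    "radius_px": 250
  }
}
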