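# Precomputed ring-closure torsion patterns used by the fixture generator:
# for each cyclic span length, period-2 (phi1, psi1, phi2, psi2) patterns
# whose ideal-geometry backbone chain is self-avoiding with the terminal
# Calpha pair at disulfide-bridging distance, screened for robust
# construction under torsion jitter.  Regenerate with solve_ring_torsions().

RING_TORSION_TABLE <- list(
  "3" = rbind(
    c(-109.109, -31.470, 80.127, 1.940),
    c(-49.993, -28.376, 80.593, 0.710),
    c(70.007, -28.376, 80.593, 0.710),
    c(130.891, -31.470, 80.127, 1.940),
    c(-109.566, 153.694, 81.627, -2.407),
    c(-49.566, 153.694, 81.627, -2.407),
    c(70.434, 153.694, 81.627, -2.407),
    c(130.434, 153.694, 81.627, -2.407)
  ),
  "4" = rbind(
    c(-122.469, -17.722, -77.704, -10.477),
    c(78.661, 15.313, 75.143, 56.535),
    c(130.862, -24.438, 69.846, 11.965),
    c(63.212, 37.571, -57.864, 99.210),
    c(-113.601, 25.531, 74.973, -66.305),
    c(110.219, -17.684, -68.107, 92.049),
    c(-132.745, 56.163, -43.329, -49.582),
    c(-112.451, 6.528, 83.106, -63.656)
  ),
  "5" = rbind(
    c(52.706, 59.334, 96.083, 119.614),
    c(122.577, -32.604, -87.241, 5.866),
    c(-59.159, -23.248, -84.362, -126.540),
    c(-114.097, -126.586, -90.758, 9.506),
    c(-111.578, 68.490, 99.348, -23.397),
    c(122.832, 64.191, 99.704, -16.230),
    c(69.593, -111.740, -75.241, 95.944),
    c(-99.002, -43.682, -95.144, -14.026)
  ),
  "6" = rbind(
    c(-119.125, 151.740, 91.053, -118.863),
    c(55.706, -115.819, -93.680, 126.185),
    c(121.631, -116.126, -85.666, 116.617),
    c(-121.783, -30.600, 100.068, 3.930),
    c(126.217, 152.510, 87.145, 4.909),
    c(121.836, -25.555, 96.185, 117.985),
    c(120.858, -26.616, -83.539, -9.349),
    c(-114.944, 65.276, 105.456, -29.879)
  ),
  "7" = rbind(
    c(125.094, 155.642, 94.207, -7.209),
    c(126.401, -26.546, 93.124, 126.713),
    c(-112.312, -33.543, -90.021, -115.200),
    c(-120.052, -19.598, 100.045, 4.684),
    c(-115.335, 158.920, 106.838, -125.349),
    c(-32.251, 141.613, 86.282, 112.845),
    c(-76.445, -16.212, 98.725, -4.888)
  ),
  "8" = rbind(
    c(-75.723, -22.077, 98.735, 4.229),
    c(-78.948, 171.665, -83.003, 7.815),
    c(-119.938, 173.919, 101.093, -151.707),
    c(22.998, 58.544, 24.164, -116.115),
    c(106.820, 170.692, 104.633, -35.192),
    c(140.018, -18.576, 82.386, 134.595),
    c(-43.045, 157.050, 105.448, 121.645),
    c(-124.276, 2.101, -65.397, -147.178)
  ),
  "9" = rbind(
    c(-123.567, -179.898, 104.856, -158.159),
    c(-51.385, 164.665, 109.087, 121.690),
    c(141.556, -23.370, 79.844, 143.570),
    c(146.690, 155.154, -84.594, 132.795),
    c(-113.237, 2.558, -60.038, -167.880),
    c(107.512, 143.045, -69.017, 168.321),
    c(142.292, -171.135, -115.978, 141.816),
    c(-61.683, -24.309, 89.246, 3.321)
  ),
  "10" = rbind(
    c(-54.536, -31.644, 93.176, 0.113),
    c(-55.442, 150.522, -78.996, -1.782),
    c(77.071, 25.813, -83.592, -20.553),
    c(-128.429, 179.244, 113.457, -161.977),
    c(-47.391, 168.181, 113.512, 108.804),
    c(-136.565, -94.564, 38.374, -145.843),
    c(144.501, -30.531, 81.561, 149.396),
    c(96.758, 175.818, 118.274, -40.997)
  ),
  "11" = rbind(
    c(-76.385, 21.209, -76.094, 137.876),
    c(-135.871, -174.754, 114.282, -160.584),
    c(149.123, -30.768, 76.493, 151.322),
    c(147.980, 134.408, -78.229, 144.033),
    c(-63.852, 152.970, -92.908, 9.689),
    c(-60.717, -23.525, 87.586, 14.515)
  ),
  "12" = rbind(
    c(-50.345, -28.355, 78.181, 4.938),
    c(-53.198, 146.280, -87.562, 5.588),
    c(64.162, 45.322, -93.856, -20.591),
    c(-129.236, -173.634, 116.994, -172.284),
    c(-52.216, 176.748, 117.266, 103.647),
    c(147.336, -30.740, 72.635, 158.247),
    c(151.003, 136.034, -84.280, 146.804),
    c(104.589, -166.004, 113.056, -55.452)
  ),
  "13" = rbind(
    c(-84.419, 29.277, -75.980, 135.356),
    c(-60.570, 175.722, 123.355, 108.603),
    c(-132.501, -169.543, 117.343, -173.103),
    c(150.299, -36.008, 74.809, 160.397),
    c(151.017, 138.635, -90.300, 151.608),
    c(141.829, 46.039, -83.219, -97.338)
  ),
  "14" = rbind(
    c(62.685, 154.131, -97.186, -111.923),
    c(-47.679, 139.287, -89.074, 6.351),
    c(72.429, 33.206, -71.836, -33.712),
    c(-78.643, 43.978, -89.790, 123.690),
    c(-59.176, -179.205, 122.017, 103.909),
    c(-138.721, -160.398, 112.565, -169.748),
    c(152.480, -32.202, 67.609, 161.724),
    c(154.040, 129.274, -85.164, 151.728)
  ),
  "15" = rbind(
    c(65.696, 153.722, -100.204, -111.940),
    c(-85.393, 38.891, -80.643, 128.121),
    c(-58.095, -177.501, 123.645, 99.624),
    c(-138.274, -163.299, 118.157, -173.871),
    c(136.902, 53.021, -84.654, -99.906),
    c(155.029, 133.866, -92.125, 154.538),
    c(156.361, -31.102, 63.651, 161.214),
    c(-93.999, 63.270, -106.305, 134.635)
  ),
  "16" = rbind(
    c(66.787, 150.220, -99.646, -110.715),
    c(-48.273, 126.663, -83.372, 10.580),
    c(60.381, 35.869, -69.942, -27.580),
    c(-79.831, 38.280, -78.270, 119.559),
    c(-63.006, -175.242, 124.478, 102.682),
    c(135.003, 59.259, -88.815, -101.248),
    c(-133.733, -157.022, 113.982, 179.596),
    c(156.357, 135.869, -96.462, 156.364)
  ),
  "17" = rbind(
    c(69.858, 148.736, -100.852, -111.744),
    c(-82.440, 35.553, -72.958, 120.101),
    c(133.345, 59.376, -86.756, -102.037),
    c(-65.069, -174.024, 125.913, 102.672),
    c(-139.838, -163.493, 123.219, -177.796),
    c(157.359, 126.796, -90.217, 157.166)
  ),
  "18" = rbind(
    c(66.206, 142.653, -96.854, -106.246),
    c(74.619, -45.595, 82.617, -108.593),
    c(-42.358, 125.162, -86.422, 8.728),
    c(59.918, 40.569, -70.038, -31.670),
    c(-81.659, 39.561, -75.490, 116.626),
    c(131.833, 59.255, -84.697, -102.689),
    c(-64.758, -171.008, 125.129, 100.527),
    c(-139.154, -162.330, 123.943, 179.440)
  ),
  "19" = rbind(
    c(68.110, 140.893, -97.186, -106.550),
    c(-92.918, -104.523, 65.764, 136.628),
    c(130.424, 58.953, -82.658, -103.209),
    c(-101.360, 54.541, -87.823, 133.432),
    c(-143.670, -167.465, 131.315, -178.784),
    c(168.901, -38.178, 63.068, 159.684)
  ),
  "20" = rbind(
    c(-42.637, -37.849, 65.500, 17.542),
    c(44.490, 55.448, -83.022, -21.122),
    c(-88.306, 41.410, -73.652, 119.543),
    c(-94.772, -106.870, 69.545, 136.539),
    c(-103.152, 59.437, -91.410, 133.107)
  ),
  "21" = rbind(
    c(-93.237, -112.810, 76.090, 132.904),
    c(-102.274, 64.681, -95.773, 130.285),
    c(163.183, -38.995, 61.841, 168.722)
  ),
  "22" = rbind(
    c(-40.209, 129.014, -97.765, 12.912),
    c(49.011, 56.547, -80.458, -28.243),
    c(-83.558, -114.324, 77.705, 121.163),
    c(-105.823, 64.222, -93.668, 132.445),
    c(-93.571, -37.890, 57.816, 70.389)
  ),
  "23" = rbind(
    c(127.407, 63.097, -81.591, -106.496),
    c(-60.758, -169.086, 131.806, 88.253),
    c(-142.954, -179.558, 148.979, 172.947)
  ),
  "24" = rbind(
    c(76.341, 147.914, -111.834, -107.079),
    c(125.155, 62.637, -80.041, -105.477),
    c(-104.993, 63.234, -90.536, 129.133)
  ),
  "25" = rbind(
    c(-83.493, -101.471, 69.033, 118.118),
    c(-141.619, 177.971, 153.483, 169.048),
    c(-79.852, 40.155, -67.254, 104.112),
    c(127.548, 66.965, -83.434, -109.230),
    c(-63.934, -166.402, 131.710, 89.706)
  ),
  "26" = rbind(
    c(-78.890, 38.585, -64.916, 102.388),
    c(47.637, 58.471, -77.694, -31.011),
    c(74.827, 145.241, -111.385, -103.460),
    c(47.596, 58.302, -77.393, -31.070)
  ),
  "27" = rbind(
    c(126.943, -22.211, 7.982, -102.555),
    c(73.870, 149.044, -116.064, -101.045),
    c(-83.914, -98.819, 68.375, 116.571),
    c(127.156, 70.667, -85.592, -110.840),
    c(-103.582, 63.287, -88.036, 124.568),
    c(53.521, -107.169, 135.591, -70.631),
    c(136.552, -115.311, 95.433, -108.668),
    c(-141.903, -178.334, 151.595, 167.726)
  ),
  "28" = rbind(
    c(-78.213, 47.287, -72.334, 98.947),
    c(50.033, 54.158, -71.163, -34.757),
    c(79.017, -52.860, 78.160, -99.380),
    c(-78.130, 47.225, -72.334, 98.934),
    c(50.042, 54.100, -71.172, -34.703)
  ),
  "29" = rbind(
    c(-106.738, 63.595, -86.615, 125.999),
    c(-60.221, -168.043, 137.488, 81.862),
    c(-140.961, -158.342, 132.814, 167.350)
  ),
  "30" = rbind(
    c(80.051, -52.951, 76.732, -98.826),
    c(-105.545, 62.754, -85.301, 124.223),
    c(79.825, -52.362, 76.183, -98.697),
    c(-32.267, 118.681, -95.791, 11.113),
    c(-82.069, 49.930, -73.526, 101.195),
    c(47.739, 53.897, -69.580, -33.768),
    c(-105.591, 62.950, -85.385, 124.120)
  ),
  "31" = rbind(
    c(-105.317, 64.463, -86.387, 123.054),
    c(131.345, -119.312, 102.286, -107.046),
    c(167.833, 131.479, -110.581, 165.744)
  )
)
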