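{
  "id": "NM_177438_synthetic_surrogate",
  "exons": [
    [1, 160],
    [161, 290],
    [291, 477],
    [478, 608],
    [609, 745],
    [746, 980],
    [981, 1120],
    [1121, 1281],
    [1282, 1509],
    [1510, 1752],
    [1753, 1960],
    [1961, 2293],
    [2294, 2647],
    [2648, 2888],
    [2889, 3113],
    [3114, 3314],
    [3315, 3540],
    [3541, 3844],
    [3845, 4044],
    [4045, 4241],
    [4242, 4503],
    [4504, 4836],
    [4837, 5095],
    [5096, 5364],
    [5365, 5593],
    [5594, 5766]
  ],
  "n_introns": 26,
  "domains": {
    "Helicase": [1, 605],
    "DUF283": [630, 722],
    "PAZ": [880, 1040],
    "RNase IIIa": [1276, 1403],
    "RNase IIIb": [1666, 1824],
    "dsRBD": [1849, 1915]
  },
  "hotspots": [
    [
      1705,
      "E"
    ],
    [
      1709,
      "D"
    ],
    [
      1809,
      "G"
    ],
    [
      1810,
      "D"
    ],
    [
      1813,
      "E"
    ]
  ]
}
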