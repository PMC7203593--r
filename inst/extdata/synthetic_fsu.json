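{
  "type": "segment",
  "units": {
    "length": "m",
    "facet_local": "mm"
  },
  "bodies": [
    {
      "name": "L4",
      "com": [0, 0, 0.04],
      "points": {
        "ALL": [0, -0.0252344913368579, 0.0301278761003632],
        "PLL": [0, 0.0200728533633519, 0.0295917922100052],
        "FL": [0, 0.0347016819310375, 0.0296016103150323],
        "ISL": [0, 0.0554446752686054, 0.0318392022075132],
        "SSL": [0, 0.0701291140438989, 0.0324382137295324],
        "CL_left": [0.025, 0.0297059745748993, 0.028323443247471],
        "CL_right": [-0.025, 0.0297059745748993, 0.028323443247471],
        "ITL_left": [0.04, 0.0151870228466578, 0.0301158962817863],
        "ITL_right": [-0.04, 0.0151870228466578, 0.0301158962817863]
      }
    },
    {
      "name": "L5",
      "com": [0, 0, 0],
      "points": {
        "ALL": [0, -0.0252344913368579, 0.00987212389963679],
        "PLL": [0, 0.0200728533633519, 0.0104082077899948],
        "FL": [0, 0.0347016819310375, 0.0103983896849677],
        "ISL": [0, 0.0554446752686054, 0.00816079779248685],
        "SSL": [0, 0.0701291140438989, 0.00756178627046756],
        "CL_left": [0.025, 0.0297059745748993, 0.011676556752529],
        "CL_right": [-0.025, 0.0297059745748993, 0.011676556752529],
        "ITL_left": [0.04, 0.0151870228466578, 0.00988410371821374],
        "ITL_right": [-0.04, 0.0151870228466578, 0.00988410371821374]
      }
    }
  ],
  "segments": [
    {
      "cranial": "L4",
      "caudal": "L5",
      "disk_centre": [0, 0, 0.02],
      "csa": 0.0018,
      "ligaments": [
        {
          "name": "ALL",
          "side": "midline",
          "cranial_point": ["L4", "ALL"],
          "caudal_point": ["L5", "ALL"],
          "prestrain": 8
        },
        {
          "name": "PLL",
          "side": "midline",
          "cranial_point": ["L4", "PLL"],
          "caudal_point": ["L5", "PLL"],
          "prestrain": 10
        },
        {
          "name": "FL",
          "side": "midline",
          "cranial_point": ["L4", "FL"],
          "caudal_point": ["L5", "FL"],
          "prestrain": 10
        },
        {
          "name": "ISL",
          "side": "midline",
          "cranial_point": ["L4", "ISL"],
          "caudal_point": ["L5", "ISL"],
          "prestrain": 4
        },
        {
          "name": "SSL",
          "side": "midline",
          "cranial_point": ["L4", "SSL"],
          "caudal_point": ["L5", "SSL"],
          "prestrain": -6
        },
        {
          "name": "CL",
          "side": "left",
          "cranial_point": ["L4", "CL_left"],
          "caudal_point": ["L5", "CL_left"],
          "prestrain": 10
        },
        {
          "name": "CL",
          "side": "right",
          "cranial_point": ["L4", "CL_right"],
          "caudal_point": ["L5", "CL_right"],
          "prestrain": 10
        },
        {
          "name": "ITL",
          "side": "left",
          "cranial_point": ["L4", "ITL_left"],
          "caudal_point": ["L5", "ITL_left"],
          "prestrain": 10
        },
        {
          "name": "ITL",
          "side": "right",
          "cranial_point": ["L4", "ITL_right"],
          "caudal_point": ["L5", "ITL_right"],
          "prestrain": 10
        }
      ],
      "facets": {
        "left": {
          "coef": {
            "p30": -0.00586075589157428,
            "p03": -0.00621322596478458,
            "p20": -0.161473134881763,
            "p02": -0.197277734790503,
            "p00": 0.0565107935289393
          },
          "frame": {
            "origin": [0.022, 0.032, 0.02],
            "axes": [
              [0.6, 0, -0.8],
              [-0, 1, 0],
              [0.8, 0, 0.6]
            ]
          },
          "stiffness": 12000,
          "damping": 4000,
          "probe_points": [
            [0.0224452086348232, 0.032, 0.0203339064761174],
            [0.0228759401825245, 0.033, 0.0187819551368934],
            [0.0211175294258827, 0.031, 0.021213147069412]
          ],
          "xy_domain": [
            [-3, -2.5],
            [3, 2.5]
          ]
        },
        "right": {
          "coef": {
            "p30": 0.00586075589157428,
            "p03": -0.00621322596478458,
            "p20": -0.161473134881763,
            "p02": -0.197277734790503,
            "p00": 0.0565107935289393
          },
          "frame": {
            "origin": [-0.022, 0.032, 0.02],
            "axes": [
              [0.6, 0, 0.8],
              [0, 1, -0],
              [-0.8, 0, 0.6]
            ]
          },
          "stiffness": 12000,
          "damping": 4000,
          "probe_points": [
            [-0.0224452086348232, 0.032, 0.0203339064761174],
            [-0.0228759401825245, 0.033, 0.0187819551368934],
            [-0.0211175294258827, 0.031, 0.021213147069412]
          ],
          "xy_domain": [
            [-3, -2.5],
            [3, 2.5]
          ]
        }
      }
    }
  ]
}
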