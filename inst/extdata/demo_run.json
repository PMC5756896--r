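{
  "seed": 7,
  "window": [0, 600],
  "scenario": {
    "birds": [
      {"individual_id": "RYB", "post_xy": [15, 8], "gap_mean": 5,
       "movement_radius": 2},
      {"individual_id": "RGY", "post_xy": [45, 30], "gap_mean": 5}
    ],
    "interaction": {"mode": "avoider", "suppression": 0.2,
                    "targets": [["RGY", "RYB"]]},
    "noise": {"azimuth_sd": 2, "begin_jitter_max": 2, "end_jitter_sd": 0.3,
              "miss_prob": 0.05, "clutter_rate": 1}
  },
  "geometry": [
    {"array_id": "1", "x": 0, "y": 0},
    {"array_id": "2", "x": 60, "y": 0},
    {"array_id": "3", "x": 30, "y": 40}
  ],
  "posts": [
    {"individual_id": "RYB", "center_xy": [15, 8], "radius": 15},
    {"individual_id": "RGY", "center_xy": [45, 30], "radius": 10}
  ],
  "analysis_windows": [[0, 300], [300, 600]],
  "n_rand": 1000,
  "n_boot": 2000
}
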