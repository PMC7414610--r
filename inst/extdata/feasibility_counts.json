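{
  "description": "Acquisition feasibility counts for hand-held OCT cpRNFL imaging: eyes attempted / imageable per group, exclusion factors, and per-quadrant success percentages on the imageable-eyes basis.",
  "groups": [
    {
      "group": "glaucoma",
      "eyes_attempted": 256,
      "eyes_possible": 188,
      "factor_counts": {
        "nystagmus": 24,
        "cloudy_opaque_media": 30,
        "high_refractive_error": 10,
        "small_pupils": 2,
        "other": 2
      },
      "success_percent_possible": {
        "nasal": 85.1,
        "temporal": 88.8,
        "inferior": 82.4,
        "superior": 77.1,
        "full": 67.0
      }
    },
    {
      "group": "controls",
      "eyes_attempted": 360,
      "eyes_possible": 360,
      "factor_counts": {},
      "success_percent_possible": {
        "nasal": 97.2,
        "temporal": 98.6,
        "inferior": 92.8,
        "superior": 93.6,
        "full": 88.9
      }
    }
  ]
}
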