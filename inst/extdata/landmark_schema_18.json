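{
  "comment": "Default 18-landmark facial schema: standard anthropometric names. Left (_l) is the subject's anatomical left, at x > 0 in the aligned frame (midsagittal plane x = 0, +y superior, +z anterior).",
  "midline": ["nasion", "pronasale", "subnasale", "labiale_superius",
              "labiale_inferius", "pogonion"],
  "pairs": [
    ["endocanthion_l", "endocanthion_r"],
    ["exocanthion_l", "exocanthion_r"],
    ["alare_l", "alare_r"],
    ["cheilion_l", "cheilion_r"],
    ["zygion_l", "zygion_r"],
    ["gonion_l", "gonion_r"]
  ]
}
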