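{
  "seed": 7,
  "layout": {
    "field_width_nm": 3000,
    "field_height_nm": 3000,
    "pitch_nm": 300
  },
  "population": {
    "occupancy": 0.20,
    "ldl_rate": 0.2
  },
  "render": {
    "pixel_size_nm": 5,
    "noise_sd_nm": 0.3,
    "line_offset_sd_nm": 0.2
  }
}
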