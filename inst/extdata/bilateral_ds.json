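{
  "frequency_mhz": 3,
  "media": {
    "water": {"density_kg_m3": 1000, "c_long_m_s": 1500},
    "lens":  {"density_kg_m3": 1180, "c_long_m_s": 2700, "c_shear_m_s": 1160},
    "skull": {"density_kg_m3": 1912, "c_long_m_s": 2300, "c_shear_m_s": 1626}
  },
  "lens": {
    "aperture_mm": [10, 10],
    "pixel_width_mm": 0.25,
    "base_thickness_mm": 0.8,
    "h_max_mm": 1.2,
    "print_resolution_mm": 0.1
  },
  "skull": {"thickness_mm": 0.25, "standoff_mm": 0.5},
  "targets": [
    {"center_mm": [1.5, 0, 3.5], "amplitude": 1, "n_sources": 100},
    {"center_mm": [-1.5, 0, 3.5], "amplitude": 1, "n_sources": 100}
  ],
  "holography": {
    "seed": 1234,
    "jitter_radius_mm": 0.25,
    "mirror_x": true,
    "plane_spacing_mm": 0.125
  },
  "grid": {
    "x_mm": [-2.5, 2.5],
    "y_mm": [-0.5, 0.5],
    "z_mm": [2.5, 5.5],
    "spacing_mm": 0.125
  },
  "pulse": {
    "ff_mhz": 3, "prf_hz": 500, "tbd_ms": 0.4,
    "sd_s": 1, "isi_s": 4, "session_min": 20
  }
}
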