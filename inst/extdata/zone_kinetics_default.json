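{
  "dorsal":  {"amplitude_light": 0.15, "amplitude_dark": 1.00, "tau_light": 0.30, "tau_dark": 0.50},
  "nasal":   {"amplitude_light": 0.50, "amplitude_dark": 0.90, "tau_light": 0.40, "tau_dark": 0.50},
  "ventral": {"amplitude_light": 0.10, "amplitude_dark": 0.60, "tau_light": 0.30, "tau_dark": 0.40},
  "sz":      {"amplitude_light": 1.00, "amplitude_dark": 0.50, "tau_light": 1.50, "tau_dark": 0.40}
}
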