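{
  "comment": "Example climate scenario. Baselines are the published 1958-2001 Aegean monthly means; p25/p75/max are the published seasonal warming increments. The p50 increments below are SYNTHETIC placeholders (the medians were never published) so that '50% projection' runs can be demonstrated.",
  "baseline": {"1": 9.2, "3": 11.9, "4": 15.9, "5": 21.3, "6": 26.2},
  "p25": {"winter": 1.5, "spring": 2.1, "summer": 2.3},
  "p50": {"winter": 2.0, "spring": 2.4, "summer": 2.8},
  "p75": {"winter": 2.4, "spring": 2.7, "summer": 3.3},
  "max": {"winter": 3.0, "spring": 3.7, "summer": 5.5}
}
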