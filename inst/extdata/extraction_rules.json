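{
  "composition": {
    "transgender_sex_gap": 2,
    "biological_sex_gap": 2,
    "lone_transgender": "TRANSGENDER_ALL",
    "lone_biological": "BIOLOGICAL_ALL",
    "two_gender": "BIOLOGICAL_ALL"
  },
  "verification": {
    "partner_gap": 2,
    "negation_window": 4
  },
  "sections": {
    "inclusion_header": "(?i)inclusion\\s+criteria|inclusion\\s*:|included\\s+if",
    "exclusion_header": "(?i)exclusion\\s+criteria|exclusion\\s*:|excluded\\s+if"
  },
  "slot_typing": {
    "birth_cues": ["birth", "assigned", "natal"],
    "max_slot_tokens": 10
  }
}
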