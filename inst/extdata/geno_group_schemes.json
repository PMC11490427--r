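{
  "D5S818": {
    "A": {"Group1": ["(10,11)", "(11,13)"], "Group2": ["(11,12)", "(12,12)"], "Group3": ["(11,11)", "(12,13)", "(13,13)"]},
    "B": {"Group1": ["(11,11)"], "Group2": ["(11,12)", "(12,12)", "(12,13)"], "Group3": ["(10,11)", "(11,13)"], "Group4": ["(13,13)"]},
    "C": {"Group1": ["(11,11)", "(13,13)"], "Group2": ["(11,12)", "(12,12)", "(12,13)"], "Group3": ["(10,11)", "(11,13)"]},
    "F": {"Group1": ["(10,11)", "(11,13)"], "Group2": ["(11,11)", "(12,12)"], "Group3": ["(11,12)", "(12,13)", "(13,13)"]},
    "H": {"Group1": ["(10,11)", "(11,11)"], "Group2": ["(11,12)", "(12,12)"], "Group3": ["(11,13)", "(12,13)", "(13,13)"]},
    "J": {"Group1": ["(10,11)", "(11,12)"], "Group2": ["(11,11)", "(12,12)"], "Group3": ["(11,13)", "(12,13)", "(13,13)"]}
  },
  "D18S51": {
    "A": {"Group1": ["(12,14)", "(12,15)"], "Group2": ["(12,16)", "(13,16)"], "Group3": ["(13,14)", "(14,15)"]},
    "C": {"Group1": ["(12,14)", "(12,15)"], "Group2": ["(12,16)", "(13,14)"], "Group3": ["(13,16)", "(14,15)"]},
    "E": {"Group1": ["(12,14)", "(12,15)", "(13,14)"], "Group2": ["(12,16)"], "Group3": ["(13,16)", "(14,15)"]},
    "F": {"Group1": ["(12,14)", "(13,14)"], "Group2": ["(12,15)", "(12,16)"], "Group3": ["(13,16)", "(14,15)"]},
    "G": {"Group1": ["(12,14)", "(12,15)"], "Group2": ["(12,16)"], "Group3": ["(13,14)", "(13,16)", "(14,15)"]}
  }
}
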