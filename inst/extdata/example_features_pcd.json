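[
  {
    "name": "situs anomaly",
    "pattern": "(s|S)itus (inversus|ambiguous)|(d|D)extrocardia|(h|H)eterotaxy",
    "case_sensitive": true
  },
  {
    "name": "denies shortness of breath",
    "pattern": "(without|(N|n)o\\b|(N|n)egative|(D|d)enies).{1,25}shortness of breath",
    "case_sensitive": true
  },
  {
    "name": "ear tubes",
    "pattern": "(E|e)ar tubes?|tympanoplasty|P\\.?E\\.? tubes?",
    "case_sensitive": true
  }
]
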