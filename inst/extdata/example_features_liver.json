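[
  {
    "name": "fatty liver disease",
    "pattern": "((NAFLD|((non[0]?alcoholic)?\\sfatty\\sliver\\s(disease)?)|K76\\.0))",
    "case_sensitive": true
  },
  {
    "name": "insulin dependence",
    "pattern": "insulin\\W+depend\\w+",
    "case_sensitive": true
  },
  {
    "name": "simple diabetes mention",
    "pattern": "(D|d)iabetes",
    "case_sensitive": true
  }
]
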