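[
  {
    "name": "significant fibroids",
    "pattern": "([Mm]ultiple |[Pp]rominent |[Ll]arge )([Uu]terine |[Ii]ntramural )?fibroid(s)?",
    "case_sensitive": true
  },
  {
    "name": "denies pelvic pain",
    "pattern": "(denies|no).{0,35}pelvic pain",
    "case_sensitive": true
  },
  {
    "name": "vaginal bleeding near fibroids",
    "pattern": "([Pp]ost(\\s|.)?menopausal |[Hh]eavy |[Aa]bnormal |[Ee]xtended )(vaginal )?bleeding\\s.{1,750}fibroid(s)?",
    "case_sensitive": true
  }
]
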