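[
  {
    "class_name": "top_4atom",
    "include_pattern": null,
    "exclude_patterns": [],
    "score_window": [25, 27],
    "comment": "top-ranked pseudo-class: no structural query, score window only"
  },
  {
    "class_name": "oxadiazole_125",
    "include_pattern": "c1cnon1",
    "exclude_patterns": [],
    "score_window": [15, 19]
  },
  {
    "class_name": "pyrrole",
    "include_pattern": "n1cccc1",
    "exclude_patterns": ["c1ccc2c(c1)ccn2"],
    "score_window": [16, 22],
    "comment": "pyrroles, indoles excluded"
  },
  {
    "class_name": "pyridine",
    "include_pattern": "c1ccncc1",
    "exclude_patterns": ["c1ccc2c(c1)cccn2"],
    "score_window": [21, 23],
    "comment": "pyridines; quinolines excluded, isoquinolines qualify"
  },
  {
    "class_name": "thiazole",
    "include_pattern": "c1cscn1",
    "exclude_patterns": [],
    "score_window": [19, 21],
    "comment": "benzothiazoles included"
  },
  {
    "class_name": "pyrimidine",
    "include_pattern": "c1cncnc1",
    "exclude_patterns": ["c1ccc2c(c1)cncn2"],
    "score_window": [19, 21],
    "comment": "pyrimidines, quinazolines excluded"
  },
  {
    "class_name": "quinoline",
    "include_pattern": "c1ccc2c(c1)cccn2",
    "exclude_patterns": [],
    "score_window": [20, 21]
  },
  {
    "class_name": "thiophene",
    "include_pattern": "c1ccsc1",
    "exclude_patterns": [],
    "score_window": [18, 22],
    "comment": "benzothiophenes included"
  },
  {
    "class_name": "indole",
    "include_pattern": "c1ccc2c(c1)ccn2",
    "exclude_patterns": [],
    "score_window": [20, 22]
  },
  {
    "class_name": "furan",
    "include_pattern": "c1ccoc1",
    "exclude_patterns": ["c1ccc2c(c1)cco2"],
    "score_window": [17, 21],
    "comment": "furans, benzofurans excluded"
  },
  {
    "class_name": "pyridyl_cation",
    "include_pattern": "c1cc[n+]cc1",
    "exclude_patterns": [],
    "score_window": null,
    "comment": "kept for completeness; typically an empty class in neutral libraries"
  },
  {
    "class_name": "quinazoline",
    "include_pattern": "c1ccc2c(c1)cncn2",
    "exclude_patterns": ["O=c1ncnc2ccccc12"],
    "score_window": [16, 20],
    "comment": "quinazolines, quinazolinones excluded"
  },
  {
    "class_name": "benzofuran",
    "include_pattern": "c1ccc2c(c1)cco2",
    "exclude_patterns": [],
    "score_window": [19, 21]
  }
]
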