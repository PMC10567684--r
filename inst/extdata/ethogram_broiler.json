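{
  "behaviors": [
    {"name": "Roosting", "class": "static", "ontology_id": "ATOL_0000837"},
    {"name": "Resting", "class": "static", "ontology_id": "ATOL_0000816"},
    {"name": "Sleeping", "class": "static", "ontology_id": "ATOL_0000873"},
    {"name": "Walking", "class": "active", "ontology_id": "ATOL_0000805"},
    {"name": "Running", "class": "active", "ontology_id": "ATOL_0000806"},
    {"name": "Hiding", "class": "active", "ontology_id": "ATOL_0000814"},
    {"name": "Feed pecking", "class": "eat", "ontology_id": "ATOL_0000363"},
    {"name": "Drinking", "class": "eat", "ontology_id": "ATOL_0000361"},
    {"name": "Grass pecking", "class": "eat", "ontology_id": "ATOL_0000844"},
    {"name": "Other pecking", "class": "eat", "ontology_id": "ATOL_0000845"},
    {"name": "Self-grooming", "class": "comfort", "ontology_id": "ATOL_0000823",
     "aliases": ["Preening"]},
    {"name": "Scratching", "class": "comfort", "ontology_id": "ATOL_0000360"},
    {"name": "Stretching", "class": "comfort", "ontology_id": "ATOL_0000822"},
    {"name": "Wing flapping", "class": "comfort", "ontology_id": "ATOL_0000822",
     "aliases": ["Wings flapping"]},
    {"name": "Swelling", "class": "comfort", "ontology_id": "ATOL_0005361",
     "aliases": ["Fluffing"]},
    {"name": "Dust bathing", "class": "comfort", "ontology_id": "ATOL_0000824"},
    {"name": "Attacking", "class": "interaction", "ontology_id": "ATOL_0000813"},
    {"name": "Escaping", "class": "interaction"},
    {"name": "Allo-grooming", "class": "interaction", "ontology_id": "ATOL_0000826",
     "aliases": ["Allopreening"]},
    {"name": "Others", "class": "other", "excluded_from_binning": true}
  ]
}
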