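# Default vocabulary used by the metadata audit. Every list can be replaced
# wholesale by pointing read_lexicons() at a modified copy of this file.
# Tag lists are matched case-insensitively against attribute tags; term lists
# and patterns are matched against free-text fields (Description, title).
geo_dedicated_tags:
  - geographic location (region and locality)
  - geographic location (country and/or sea)
  - geographic location (latitude)
  - geographic location (longitude)
  - lat_lon
  - geo_loc_name
date_dedicated_tags:
  - date
  - collection date
  - collection_date
  - sample date
tissue_dedicated_tags:
  - tissue
  - organism part
  - tissue_type
  - tissue type
voucher_tags:
  - specimen voucher
  - specimen_voucher
  - biological material
  - bio_material
  - culture_collection
tissue_terms:
  - bone
  - tooth
  - teeth
  - petrous
  - dentine
  - dentin
  - enamel
  - cementum
  - calculus
  - hair
  - skin
  - muscle
  - antler
  - tusk
  - ivory
  - eggshell
  - feather
  - horn
  - hoof
  - phalanx
  - femur
  - cranium
  - mandible
  - rib
  - vertebra
gazetteer_terms:
  - Norfolk
  - United Kingdom
  - England
  - Scotland
  - Ireland
  - France
  - Germany
  - Spain
  - Portugal
  - Italy
  - Sweden
  - Norway
  - Denmark
  - Estonia
  - Latvia
  - Lithuania
  - Poland
  - Hungary
  - Romania
  - Bulgaria
  - Greece
  - Turkey
  - Anatolia
  - Siberia
  - Mongolia
  - China
  - Japan
  - Kazakhstan
  - Iran
  - Israel
  - Levant
  - Egypt
  - Morocco
  - Ethiopia
  - Kenya
  - South Africa
  - Mexico
  - Peru
  - Chile
  - Argentina
  - Brazil
  - Alaska
  - Greenland
  - Iceland
  - Ukraine
  - Russia
  - Caucasus
  - Pontic steppe
  - Altai
  - Yakutia
  - Patagonia
date_patterns:
  - '\b\d[\d,.]*\s*(?:cal\.?\s*)?(?:k?a\s+)?(?:BP|bp)\b'
  - '\b\d[\d,.]*\s*(?:BCE|BC|CE|AD|cal BCE|cal CE)\b'
  - '\b(?:radiocarbon|14C|C14)[- ]?dat(?:e|ed|ing)\b'
c14_prefixes:
  - OxA
  - Beta
  - Poz
  - KIA
  - Ua
  - AAR
  - Wk
  - GrA
  - GrM
  - UBA
  - PSUAMS
  - UCIAMS
protocol_terms:
  - single-stranded
  - double-stranded
  - ssDNA
  - dsDNA
  - UDG
  - USER
  - uracil
  - partial UDG
  - non-UDG
  - blunt-end
  - size selection
protocol_tags:
  - library construction protocol
  - library_construction_protocol
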