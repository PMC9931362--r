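# Entity-selection profile: an entity is indexed when at least one rule
# matches.  statement_properties select entities carrying any statement
# with the listed property; closure_roots select every entity connected
# to the root by a chain of the listed relations.
language: de
statement_properties:
- P699    # Disease Ontology ID
- P2892   # UMLS CUI
- P486    # MeSH descriptor ID
- P672    # MeSH tree code
closure_roots:
- root: Q12140        # medication
  relations:
  - P279              # subclass of (add P31 to include instances)
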