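# Default feeding-search lexicon. The term lists are a reconstruction of the
# kind of free-text search used for Rourke-based well-baby notes; every
# category is user-overridable, so none of this content is load-bearing.
rourke_variants:
  - Rourke
  - Well Baby Visit
  - Well Baby Check Up
  - Newborn Visit
  - 1 month visit
  - 2 month visit
  - 4 month visit
  - 6 month visit
breast_terms:
  - breastfeeding
  - breast feeding
  - breastfed
  - breast fed
  - breast milk
  - breastmilk
  - nursing
  - BF
  - EBF
formula_terms:
  - formula
  - formula fed
  - bottle fed formula
  - similac
  - enfamil
mixed_markers:
  - both
  - supplementing
  - breast and formula
  - mixed
exclusivity_markers:
  - exclusively
  - exclusive
  - only
negation_markers:
  - "no"
  - "not"
  - stopped
  - weaned
  - discontinued
# Historical (past-tense) duration-bearing patterns; "{term}" stands for any
# breast term, "{n}" for an integer, "{unit}" for days/weeks/months.
historical_patterns:
  - "{term} until {n} {unit}"
  - "{term} for {n} {unit}"
  - "{term} until age {n} {unit}"
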