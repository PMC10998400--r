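# Consensus-meeting decisions. Items not named default to their round-1
# verdict: selected items are kept, discussion and not-selected items are
# dropped. The third selected-then-dropped item (question 20) is a synthetic
# placeholder: only two of the three were named in the published results.
stage: consensus_round
decisions:
  - target: "27.9"
    action: DROP
    rationale: "Content covered by the reworded quality-improvement question."
  - target: "28"
    action: DROP
    rationale: "Content covered by the reworded quality-improvement question."
  - target: "20"
    action: DROP
    rationale: "Synthetic stand-in for the unnamed third dropped item."
  - target: "2"
    action: PROMOTE
    rationale: "Reworded to years of professional activity instead of age."
  - target: "7"
    action: PROMOTE
    rationale: "Included after rewording."
  - target: "8"
    action: PROMOTE
    rationale: "Included after rewording."
  - target: "9"
    action: PROMOTE
    rationale: "Included after rewording."
  - target: "11"
    action: PROMOTE
    rationale: "Changed to use of the electronic health record."
  - target: "19"
    action: PROMOTE
    rationale: "Included after rewording."
  - target: "23.7"
    action: PROMOTE
    rationale: "Included after rewording."
  - target: "27.2"
    action: PROMOTE
    rationale: "Included after rewording."
  - target: "27.5"
    action: PROMOTE
    rationale: "Included after rewording."
  - target: "32"
    action: PROMOTE
    rationale: "Included after rewording."
  - target: "3"
    action: PROMOTE
    rationale: "Gender question retained with revised response options."
  - target: "31"
    action: PROMOTE
    rationale: "Valuable content; question reformulated."
  - action: ADD
    rationale: "New question on the payment system used."
    new_question:
      part_id: part1
      question_id: "35"
      text: "What payment system do you work with?"
      response_format: categorical
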