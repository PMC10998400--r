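# Final-evaluation decision: the researchers asked the panel to exclude one
# question because of its subjective nature. Everything else is kept.
stage: final_evaluation
decisions:
  - target: "11"
    action: DROP
    rationale: "Excluded because of the subjective nature of the question."
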