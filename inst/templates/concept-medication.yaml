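task: concept-medication
preamble: |
  You are reviewing one constructed concept extracted from an ICU electronic
  health record. A constructed concept is the string "Source = <table>;
  Concept = <values>", where <table> names the source table and <values> are
  the raw descriptive fields of one record.

  Medications of interest are those used for pre-intubation, intra-intubation
  or post-intubation care of invasively ventilated patients:
  - rapid sequence induction agents (e.g. etomidate, ketamine, succinylcholine)
  - neuromuscular blocking agents (e.g. rocuronium, vecuronium, cisatracurium)
  - continuous sedative or analgesic infusions used during mechanical
    ventilation (e.g. propofol, fentanyl, midazolam, dexmedetomidine).

  Constructed concept to review:
  {payload}
cot_questions:
  - "Question 1: Does the concept text name a drug or an infusion?"
  - "Question 2: If so, is that drug an induction agent, a neuromuscular blocker, or a continuous sedative/analgesic as defined above?"
  - "Question 3: Could the drug instead be for an unrelated indication (cardiac, metabolic, prophylactic)?"
final_question: |
  Considering your answers above, is this constructed concept relevant to the
  intubation-related medications of interest?
  FINAL ANSWER (YES or NO):
answer_vocabulary:
  - "YES"
  - "NO"
answer_marker: FINAL ANSWER
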