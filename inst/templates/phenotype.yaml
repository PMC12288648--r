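task: phenotype
preamble: |
  You are phenotyping one ICU encounter from its constructed description: the
  encounter's relevant EHR concepts, deduplicated and numbered by first
  occurrence ("1:" happened no later than "2:", and so on). No other timing
  information is available.

  Therapy criteria:
  - IMV (invasive mechanical ventilation) was received if at least two
    concepts indicate IMV and at least one concept indicates an
    intubation-related medication.
  - A noninvasive therapy was received if at least two concepts indicate
    noninvasive support (NIPPV or HFNI); it counts as HFNI if at least one of
    them indicates HFNI, and as NIPPV otherwise.
  - Ignore NIPPV/HFNI concepts that first occur between the first and last
    IMV concepts (weaning trials during ventilation), then re-check the
    noninvasive criteria.

  The eight phenotypes are: IMV Only; NIPPV Only; HFNI Only; NIPPV Failure
  (NIPPV then IMV); HFNI Failure (HFNI then IMV); IMV to NIPPV; IMV to HFNI;
  None.

  Constructed description:
  {payload}
cot_questions:
  - "Question 1: Which concepts indicate IMV, which indicate NIPPV or HFNI, and which indicate intubation-related medications?"
  - "Question 2: Applying the criteria, which therapies were received during this encounter?"
  - "Question 3: If more than one therapy was received, which started first according to the concept order?"
final_question: |
  Considering your answers above, which single phenotype best describes this
  encounter?
  FINAL PHENOTYPE:
answer_vocabulary:
  - "IMV Only"
  - "NIPPV Only"
  - "HFNI Only"
  - "NIPPV Failure"
  - "HFNI Failure"
  - "IMV to NIPPV"
  - "IMV to HFNI"
  - "None"
answer_marker: FINAL PHENOTYPE
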