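task: concept-therapy
preamble: |
  You are reviewing one constructed concept extracted from an ICU electronic
  health record. A constructed concept is the string "Source = <table>;
  Concept = <values>", where <table> names the source table and <values> are
  the raw descriptive fields of one record.

  Definitions of the respiratory support therapies of interest:
  - Invasive Mechanical Ventilation (IMV): ventilation delivered through an
    endotracheal tube or tracheostomy (e.g. "Oral ETT", "Ventilator",
    ventilator mode settings).
  - Noninvasive Positive Pressure Ventilation (NIPPV): positive pressure
    delivered by mask, such as BiPAP or CPAP (e.g. "BiPAP/CPAP").
  - High-Flow Nasal Insufflation (HFNI): heated, humidified high-flow oxygen
    through nasal cannula (e.g. "Hi Flow NC", "HFNC").

  Constructed concept to review:
  {payload}
cot_questions:
  - "Question 1: Which source table does this concept come from, and what kind of clinical information does that table record?"
  - "Question 2: Does the concept text name a device, airway, ventilator setting, or treatment used to deliver respiratory support?"
  - "Question 3: If so, does it indicate IMV, NIPPV, or HFNI as defined above, rather than routine monitoring or an unrelated therapy?"
final_question: |
  Considering your answers above, is this constructed concept relevant to any
  of the respiratory support therapies (IMV, NIPPV, or HFNI)?
  FINAL ANSWER (YES or NO):
answer_vocabulary:
  - "YES"
  - "NO"
answer_marker: FINAL ANSWER
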