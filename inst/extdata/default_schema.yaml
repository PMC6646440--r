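# Default fact schema for abdominopelvic radiology reports.
# Each fact type has exactly one anchor slot (the entity that defines the
# fact) and a set of modifier slots, each phrased as the clinical question
# the slot answers. Edit or extend freely: models size their outputs from
# this registry.
version: "1.0"
fact_types:
  - name: finding_observed
    anchor: finding
    modifiers:
      - {name: negation, question: "is the finding absent?"}
      - {name: uncertainty, question: "how certain is the finding?"}
      - {name: conditionality, question: "under what condition does the assertion hold?"}
      - {name: location, question: "where is the finding?"}
      - {name: size, question: "how large is the finding?"}
      - {name: description, question: "what does the finding look like?"}
      - {name: change_over_time, question: "how has the finding changed?"}
      - {name: temporal_qualifier, question: "when was the finding present?"}
      - {name: diagnostic_reasoning, question: "why does the radiologist believe this?"}
  - name: followup_recommendation
    anchor: recommendation
    modifiers:
      - {name: negation, question: "is follow-up explicitly not recommended?"}
      - {name: conditionality, question: "under what condition is follow-up recommended?"}
      - {name: desired_timing, question: "when should follow-up occur?"}
      - {name: location, question: "what body region should be followed up?"}
  - name: carries_diagnosis
    anchor: diagnosis
    modifiers:
      - {name: negation, question: "is the diagnosis excluded?"}
      - {name: uncertainty, question: "how certain is the diagnosis?"}
      - {name: temporal_qualifier, question: "when was the diagnosis made?"}
      - {name: person_qualifier, question: "whose diagnosis is it?"}
  - name: had_procedure
    anchor: procedure
    modifiers:
      - {name: negation, question: "is the procedure explicitly denied?"}
      - {name: temporal_qualifier, question: "when was the procedure performed?"}
      - {name: location, question: "where was the procedure performed?"}
  - name: lab_result
    anchor: lab_value
    modifiers:
      - {name: temporal_qualifier, question: "when was the lab value obtained?"}
      - {name: description, question: "what is the measured value?"}
  - name: prior_study
    anchor: prior_study
    modifiers:
      - {name: temporal_qualifier, question: "when was the prior study performed?"}
      - {name: description, question: "what kind of study was it?"}
  - name: comparison_study
    anchor: comparison
    modifiers:
      - {name: temporal_qualifier, question: "from when is the comparison study?"}
      - {name: description, question: "what kind of study is compared?"}
  - name: anatomic_region_property
    anchor: region
    modifiers:
      - {name: negation, question: "is the property absent?"}
      - {name: description, question: "what property does the region have?"}
      - {name: change_over_time, question: "has the region changed?"}
  - name: clinical_history
    anchor: history_item
    modifiers:
      - {name: negation, question: "is the history explicitly denied?"}
      - {name: temporal_qualifier, question: "when did the history occur?"}
      - {name: person_qualifier, question: "whose history is it?"}
  - name: imaging_limitation
    anchor: limitation
    modifiers:
      - {name: description, question: "what causes the limitation?"}
      - {name: location, question: "what region is limited?"}
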