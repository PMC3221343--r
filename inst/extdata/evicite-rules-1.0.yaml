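version: '1.0'
guideline_types:
- Guideline
- Practice Guideline
- Consensus Development Conference
- Consensus Development Conference, NIH
sr_types:
- Meta-Analysis
- Systematic Review
review_types:
- Review
- Scientific Integrity Review
rct_types: Randomized Controlled Trial
letter_types:
- Letter
- Comment
- Editorial
study_design_types:
- Clinical Trial
- Controlled Clinical Trial
- Clinical Trial, Phase I
- Clinical Trial, Phase II
- Clinical Trial, Phase III
- Clinical Trial, Phase IV
- Comparative Study
- Multicenter Study
- Observational Study
- Case Reports
- Evaluation Study
- Evaluation Studies
- Validation Study
- Validation Studies
- Twin Study
- Clinical Study
report_types:
- Technical Report
- Government Document
- Government Publications
other_types:
- Book
- Congress
- Abstract
- Published Erratum
- News
- Interview
- Biography
- Historical Article
- Lecture
- Address
- Bibliography
- Thesis
- Electronic Resource
report_source_patterns:
- \bMMWR\b
- Morb(idity)?\.? Mortal(ity)?\.? W(ee)?kly
- technology assessment
- task force
- working group
- statistical (data )?report
- government printing office
- office (for|of) national statistics
- \bstatistics\b.*\bgov\b
- \.gov\b
- \bAHRQ\b
- agency for healthcare research
sr_search_patterns:
- we searched
- literature search
- comprehensive search
- systematic search
- systematic review
- \bmedline\b
- \bembase\b
- \bcochrane\b
- databases? (were|was) searched
- search(ed)? (of )?(the )?(electronic )?databases?
sr_selection_patterns:
- inclusion criteria
- exclusion criteria
- eligibility criteria
- selection criteria
- criteria for (inclusion|selection)
- studies were (selected|included|eligible)
sr_synthesis_patterns:
- \bpooled\b
- meta-?analys
- data (were|was) (synthesi[sz]ed|combined)
- random-?effects
- fixed-?effects
- \bforest plot\b
- (included|identified) [0-9]+ (studies|trials|randomi[sz]ed)
study_sample_patterns:
- \bn\s*=\s*[0-9]+
- '[0-9]+\s+(patients|subjects|participants|adults|children|cases|women|men|infants)'
- \benrolled\b
- \brecruited\b
- cohort of
section_cue_groups:
  opening: '(objectives?|introduction|background|problem)\s*:'
  methods: '(methods?|subjects|design|patients and methods)\s*:'
  results: '(results?|findings)\s*:'
  closing: '(discussion|conclusions?|interpretation)\s*:'
synopsis_source_patterns:
- ACP J(ournal)?\.? Club
- \bFPIN\b
- Family Physicians Inquiries Network
- Clin(ical)? Inq(uiries)?
- Evid(ence)?.?Based (Medicine|Practice)\b
study_data_requires_structure: yes
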