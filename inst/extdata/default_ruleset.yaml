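# Default triage ruleset. Ordered: first matching rule wins; the final
# rule is the mandatory terminal default. The exact branch structure of
# published routing flowcharts varies between institutions (for example
# whether urgency alone should trigger cartridge-first testing at an
# academic center); these rules encode the commonly stated practice
# points and are meant to be replaced or reordered by each laboratory.
rules:
  - rule_id: scant_tissue_ngs_first
    match:
      tissue_adequacy: scant
    action:
      modality: ngs_first
      reflex: none
    rationale: >-
      Scant tissue may be insufficient for cartridge-based testing and is
      better spent on a conventional NGS workup.
  - rule_id: ambiguous_ngs_orthogonal
    match:
      prior_result: ngs_ambiguous
    action:
      modality: idylla_orthogonal_confirmation
      reflex: none
    rationale: >-
      An ambiguous or very low allele-frequency NGS call can be orthogonally
      confirmed by the rapid single-gene qPCR cartridge.
  - rule_id: cartridge_negative_reflex
    match:
      prior_result: idylla_negative
    action:
      modality: ngs_first
      reflex: none
    rationale: >-
      A negative hotspot-cartridge result does not exclude actionable
      variants outside the hotspot list; the sample is escalated to
      comprehensive NGS.
  - rule_id: community_first_line
    match:
      care_setting: community_no_onsite_molecular
    action:
      modality: idylla_first_line
      reflex: reflex_to_ngs_if_negative
    rationale: >-
      Sites without an on-site molecular laboratory can run the fully
      automated cartridge directly on FFPE sections; negative results are
      reflexed to send-out NGS.
  - rule_id: academic_urgent_single_gene
    match:
      care_setting: academic_with_ngs
      urgency: urgent
    action:
      modality: idylla_first_line
      reflex: reflex_to_ngs_if_negative
    rationale: >-
      When a rapid single-gene answer (for example BRAF V600 status) is
      needed for an immediate diagnostic or therapeutic decision, the
      cartridge returns a result within hours while batch NGS takes days.
  - rule_id: default_ngs_first
    match: {}
    action:
      modality: ngs_first
      reflex: none
    rationale: >-
      Comprehensive NGS remains the default for routine workup at centers
      with sequencing capacity.
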