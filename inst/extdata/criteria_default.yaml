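# Default nine-criterion evidence configuration for tiered causal-gene
# prioritization. Each HEIDI criterion requires its paired SMR criterion:
# a non-significant HEIDI p only supports a shared causal signal when the
# SMR association itself is significant.
criteria:
  - name: fin_cis_smr
    source: smr_fdr_fin
    threshold: 0.05
    direction: below
  - name: fin_cis_heidi
    source: heidi_fin
    threshold: 0.05
    direction: above
    requires: fin_cis_smr
  - name: blood_smr
    source: smr_fdr_blood
    threshold: 0.05
    direction: below
  - name: blood_heidi
    source: heidi_blood
    threshold: 0.05
    direction: above
    requires: blood_smr
  - name: rep_cis_smr
    source: smr_fdr_rep
    threshold: 0.05
    direction: below
  - name: rep_cis_heidi
    source: heidi_rep
    threshold: 0.05
    direction: above
    requires: rep_cis_smr
  - name: mr_discovery
    source: mr_p_fin
    threshold: 0.05
    direction: below
  - name: mr_replication
    source: mr_p_8cohort
    threshold: 0.05
    direction: below
  - name: coloc_pp4
    source: coloc_pp4
    threshold: 0.5
    direction: above
tier_rule:
  tier2_min: 4      # Tier 2 at >= 4 satisfied criteria (matches the
                    # integrated evidence table); set tier2_strict for > 4
  tier3_exact: 3
  tier2_strict: false
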