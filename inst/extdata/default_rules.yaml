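viral_threshold: 1.0
include_low_confidence: yes
rules:
  vs2:
    combine: max_positive
    subrules:
    - name: vs2_confident
      tier: confident
      score: 1.0
      condition: vs2_score >= 0.9
    - name: vs2_low
      tier: low_confidence
      score: 0.5
      condition: vs2_score >= 0.5 & vs2_score < 0.9
    - name: vs2_hallmark
      tier: confident
      score: 1.0
      condition: vs2_hallmark >= 1 & vs2_score >= 0.5
  vb:
    combine: max_positive
    subrules:
    - name: vb_confident
      tier: confident
      score: 1.0
      condition: vb_quality %in% c("high", "medium")
    - name: vb_low
      tier: low_confidence
      score: 0.5
      condition: vb_quality == "low"
  vs:
    combine: max_positive
    subrules:
    - name: vs_confident
      tier: confident
      score: 1.0
      condition: vs_category %in% c(1, 2)
    - name: vs_low
      tier: low_confidence
      score: 0.5
      condition: vs_category == 3
  dvf:
    combine: max_positive
    subrules:
    - name: dvf_confident
      tier: confident
      score: 1.0
      condition: dvf_score >= 0.9 & dvf_pvalue < 0.05
    - name: dvf_low
      tier: low_confidence
      score: 0.5
      condition: dvf_score >= 0.7 & dvf_score < 0.9 & dvf_pvalue < 0.05
  tna:
    combine: sum
    subrules:
    - name: tna_checkv
      tier: confident
      score: 1.0
      condition: cv_quality %in% c("complete", "high", "medium") | cv_completeness
        >= 50
    - name: tna_kaiju
      tier: low_confidence
      score: 0.5
      condition: kj_is_viral
    - name: tna_hallmark
      tier: confident
      score: 1.0
      condition: vs2_hallmark >= 2
  tnv:
    combine: sum
    subrules:
    - name: tnv_cellular
      tier: high_confidence_negative
      score: -3.0
      condition: kj_classified & !kj_is_viral & cv_viral_genes == 0
    - name: tnv_hostgenes
      tier: confident
      score: -1.0
      condition: cv_host_genes >= 2 * pmax(cv_viral_genes, 1) & cv_viral_genes <=
        1
    - name: tnv_nosignal
      tier: low_confidence
      score: -0.5
      condition: (is.na(vs2_score) | vs2_score < 0.5) & vb_quality == "none" & is.na(vs_category)
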