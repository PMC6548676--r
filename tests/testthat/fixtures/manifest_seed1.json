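{
  "outputs": {
    "item_bank.tsv": "5302d41d1d7369eae6343d2768d6664f",
    "responses.tsv": "2c21b90d3b9b1a48d60b70f2e0dc1f36",
    "covariates.tsv": "8df76bcc4a4ac440929ff150ad4ebcaa",
    "genotypes.vcf": "5169a377a3060b54c8aa1afaad4ad69d",
    "truth.tsv": "adbbc90734f3442b8e38407d631f6cd5",
    "scores.tsv": "ddacc3bb5b767e16cdc0dcff7f394d36",
    "domain_scores.tsv": "5cc913036c0a85e8edceae0f32d6f3dd",
    "assignments.tsv": "b2b32b7e620ac5b7a2bc12a1f8efcce9",
    "apoe_contingency.tsv": "151950034d2ff0fb6add6995264af807",
    "associations.tsv": "4f06d9a661a7b83c78cd35d5bf076f5c",
    "meta.tsv": "297a291e511d5c2fde07d7bf86aeeeb1",
    "suggestive_loci.tsv": "e61fd8b1d82fcdfd850bcfc3c9112861",
    "weights.tsv": "a9a7688a386f7ccee5453fae5f47e496",
    "risk_scores.tsv": "d10f4311bc76080bee34c2bc722424ba",
    "model_comparison.tsv": "c58d3d4fb1aed0df39fb1f95ac357279"
  },
  "results": {
    "distribution_chisq": 6.78908713324121,
    "distribution_df": 5,
    "apoe_overall_chisq": 19.4952240772704,
    "apoe_overall_p": 0.00155370063464884,
    "n_suggestive": 2,
    "lr_stat": 49.8592052779065,
    "lr_df": 5,
    "auc_reference": 0.575344444444444,
    "auc_subgroup": 0.639663888888889
  }
}
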