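# Annotated example configuration for `comodbm simulate` /
# sim_config(). Every key is optional; omitted keys keep the package's
# reference study-scale defaults (204 seed genes, five species, planted
# enrichment/concordance/cluster/driver structure). Matrix-valued elements
# (baseline_rates, class_rates, driver_effects, fert_allocation) are R
# objects and are overridden programmatically via sim_config(), not here.

preset: study          # "study" (planted structure) or "null" (exchangeable)
n_seed_genes: 204      # number of seed (spermatogenic-failure) genes
concordance_share: 0.6 # weight of the cross-species shared propensity, 0..1
share_high: 1.0        # shared weight for the high-concordance tier
share_high_frac: 0.3   # fraction of genes in the high-concordance tier
activity_boost: 12     # annotation-depth multiplier for that tier (non-mouse)
gamma_shape: 0.35      # shape of the gamma propensity (smaller = heavier tail)
mouse_share: 0.15      # weight of the shared propensity in mouse counts
mouse_gamma_shape: 20  # shape of the mouse private propensity
decoy_low_rate: 0.08   # rate of low-confidence decoy ortholog records
n_terms_per_category: 60   # ontology pool size per base category and species
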