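Small plain-text fixtures of published summary tables, re-entered by hand:

- gene_family_counts.tsv: per-species counts of legume gene families with
  0/1/2/3/>=4 members, for the full trees ("full") and for trees with
  recent (Ks < 0.2) same-species terminal pairs collapsed ("collapsed").
- cercidoideae_clade_counts.tsv: counts of mined Cercis/Bauhinia clade
  types and how many have a duplication-labeled MRCA.
- legume_chromosome_modes.tsv: number of legume genera per clade whose
  modal gametic chromosome number equals n (long format; n = 17 stands
  for ">16").
- genome_sizes.tsv: 2C nuclear DNA amounts in picograms.

Modal-count rows expand to per-genus records (synthetic genus names) when
fed to clade_summary(); see scripts/acceptance.R.
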