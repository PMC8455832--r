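# Default sdrkit pipeline configuration. Every key shown here can be
# overridden; unknown keys are rejected.
seed: 1
filter:
  min_aln_length: 300   # bp, strict >
  min_identity: 75      # percent, strict >
  min_bitscore: 1000    # strict >
vaf:
  min_depth: 5          # reads; sites below are masked per sample
  k: 2                  # clusters to cut the dendrogram into
repeats:
  window: 100           # bp tile
  fold_threshold: 10    # flag windows >= fold * background
  merge_gap: 500        # bp between merged flagged runs
  min_locus_len: 1000   # bp
  low_fold: 3           # sub-segmentation threshold
sdr:
  chain_gap: 20000          # bp between chained marker hits
  min_query_fraction: 0.5   # SDR query coverage to call a contig
  flank: 50000              # bp around the SDR when counting repeats
  max_span: 10000           # bp between inverted-repeat arms
  complete_fraction: 0.9    # MSL query coverage for a complete call
simulate:
  genome_size: 1000000
  n_contigs: 20
  dup_fraction: 0.45
  mismatch_rate: 130
  indel_rate: 31
  n_y: 5
  n_x: 5
  n_groups: 3
  samples_per_group: 5
  n_sites: 300
  group_divergence: 0.25
  mean_depth: 30
  dropout_prob: 0.1
  track_length: 50000
  background: 30
  noise_sd: 3
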