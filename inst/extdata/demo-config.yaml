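# End-to-end demonstration run on synthetic data (see ?runAll, ?demoConfig).
out_dir: adipochip_demo_run
seed: 1
genome:
  chr1: 6.0e6
  chr2: 4.0e6
simulate:
  n_genes: 400
  n_sites_mark: 60
  n_sites_tf: 40
  site_width: 1000
  tf_site_width: 300
  tf_offset: 300
  fold: 10
  n_reads: 5.0e5
  read_length: 36
  expression_shift: 1
  expression_sd: 1
peaks:
  extension: 200
  bin_size: 25
  p_threshold: 1.0e-9
  merge_gap: 200
  min_fold: 3
  pseudocount: 1
annotate:
  window: 10000
proximity:
  distance: 300
coloc:
  window: 1500
  bin: 100
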