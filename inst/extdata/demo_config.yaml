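# Demo run: 10 simulated cell lines over a 10-kb target, six input-mass
# levels, with the thresholds used throughout the package. Runs in minutes.
seed: 20160526
regions:
  chrom: chr1
  start: 1
  end: 10000
genotypes:
  n_lines: 10
  variant_density: 0.01
  het_prob: 0.35
  hom_prob: 0.15
library:
  total_read_pairs: 20000
  conversion_efficiency: 0.01
  on_target_fraction: 0.6
  improper_pair_fraction: 0.02
  per_base_error_rate: 0.0005
  read_span: 100
masses: [6.25, 12.5, 25.0, 50.0, 100.0, 200.0]
thresholds:
  het_window: [0.40, 0.60]
  hom_threshold: 0.90
  background_max_freq: 0.01
  genotype_min_freq: 0.10
  maf_bins: [0.0, 0.05, 0.10, 0.15, 1.0]
  min_mean_depth: 0
detector:
  min_fraction: 0.02
  min_alt_reads: 5
saturation:
  fractions: [0.1, 0.25, 0.5, 0.75, 1.0]
contamination:
  fraction: 0.005
  mass: 50
concordance:
  n_libraries: 3
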