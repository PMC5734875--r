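# shared fixtures: small noise-free panels with planted truth

clean_panel <- function(n_lines = 40, n_female = 20, n_male = 20,
                        probes = 80, seed = 11, ...) {
  generate_panel(panel_config(
    n_lines = n_lines, n_female = n_female, n_male = n_male,
    probes_per_chromosome = probes, noise_probe_fraction = 0,
    seed = seed, ...
  ))
}

# probe genotype vector with a given homozygous count out of n
geno_mix <- function(n_hom, n_het, hom = "AA") {
  c(rep(hom, n_hom), rep("AB", n_het))
}

# truth chromosome states of one line as a named copy vector
truth_copies <- function(panel, line) {
  st <- panel$truth$states
  st <- st[st$line == line, ]
  stats::setNames(st$copy, st$chrom)
}
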