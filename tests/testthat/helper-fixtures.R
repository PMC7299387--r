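# Shared fixtures: shipped tables plus small hand-built panels.

shipped_panel <- function() load_panel(grspanel_example("panel.tsv"))

shipped_freqs <- function(panel = shipped_panel()) {
  load_frequencies(grspanel_example("frequencies.tsv"), panel)
}

# Effect-allele frequencies of one population as a named vector in
# panel order.
pop_freq_vec <- function(freqs, population, panel) {
  rows <- freqs[freqs$population == population, ]
  setNames(rows$effect_allele_freq[match(panel$snp_id, rows$snp_id)],
           panel$snp_id)
}

# A 3-SNP toy panel: susceptibility per-allele, protective per-allele,
# dominant susceptibility.
toy_panel <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "snp_id\tlocus\tchromosome\teffect_allele\tother_allele\tdirection\tgenetic_model\teffect_kind\teffect_value",
    "s1\tL1\t1\tA\tG\tsusceptibility\tper_allele\todds_ratio\t2.0",
    "s2\tL2\t2\tC\tT\tprotective\tper_allele\todds_ratio\t0.5",
    "s3\tL3\t3\tT\tC\tsusceptibility\tdominant\todds_ratio\t1.5"
  ), path)
  load_panel(path)
}

# Closed-form expected mean GRS at given effect-allele frequencies:
# 2 * sum of oriented expected frequencies.
expected_mean_grs <- function(panel, freq) {
  oriented <- ifelse(panel$direction == "protective", 1 - freq, freq)
  2 * sum(oriented)
}

# Writes a minimal VCF for the toy scenarios used in reader tests.
write_test_vcf <- function(records, samples) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}
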