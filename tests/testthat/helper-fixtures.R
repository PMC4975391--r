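# Shared in-code fixtures for the test suite. Everything is built
# programmatically; no binary data.

# A deterministic SNP track with exact allele fractions (counts rounded from
# af * depth), handy for boundary tests.
make_snp_track <- function(pos, tumor_af, depth = 100, normal_af = 0.5,
                           chrom = "chr16") {
  n <- length(pos)
  depth <- rep_len(depth, n)
  tumor_af <- rep_len(tumor_af, n)
  normal_af <- rep_len(normal_af, n)
  talt <- round(tumor_af * depth)
  nalt <- round(normal_af * depth)
  data.frame(chrom = chrom, pos = pos,
             normal_ref = depth - nalt, normal_alt = nalt,
             tumor_ref = depth - talt, tumor_alt = talt,
             paired = TRUE, stringsAsFactors = FALSE)
}

# One variant-call row with overridable fields.
make_call <- function(sample_id = "S1", patient_id = "P1", gene = "TSC2",
                      variant_type = "nonsense", cdna_change = "c.100C>T",
                      protein_change = "p.Q34*", mutant_reads = 30,
                      ref_reads = 70, origin = "somatic",
                      bidirectional = TRUE) {
  depth <- mutant_reads + ref_reads
  data.frame(patient_id = patient_id, sample_id = sample_id, gene = gene,
             variant_type = variant_type, cdna_change = cdna_change,
             protein_change = protein_change, mutant_reads = mutant_reads,
             ref_reads = ref_reads, origin = origin,
             bidirectional = bidirectional,
             functional_class = NA_character_,
             uncovered = is.na(depth) | depth == 0,
             af = ifelse(is.na(depth) | depth == 0, NA_real_,
                         mutant_reads / depth),
             stringsAsFactors = FALSE)
}

cohort <- load_fixtures()
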