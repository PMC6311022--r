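loci:
- name: Du215
  motifs:
  - GATA
  min_repeats: 3
  snv_positions:
  - 6
  - 15
  - 95
  reference: CTCAGTGAACTATCCTTAATTCTCACCGGTGCCGAATTGTGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAAAGCTTGCAATGCGCATTGGAACAATACTCACTGAAGGGG
- name: Du281
  motifs:
  - GATA
  min_repeats: 3
  snv_positions:
  - 12
  reference: CGCCGGTACCGTTCTAACGTGCATTGGTAGTCCCGGCCGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATATAGTACATTGCTAGATGGCCCCACCCCAACCAGCTAAT
- name: Du323
  motifs:
  - GATA
  - AC
  min_repeats: 3
  snv_positions:
  - 8
  - 118
  reference: ATGCTGCGGCTATCGAGTGACTTGAAACCAGCAGTTAGGCGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATACCATTTACACACACACACAAAAAGAGACCACATGTTCAATACTTGGCTTCTGTCGTGA
- name: Du47G
  motifs:
  - GATA
  min_repeats: 3
  snv_positions:
  - 5
  - 13
  - 21
  - 110
  reference: ATTTCGAAGGATTGCGGGATTCCAATGCTATGGGAGCTGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATCTATTTAGTAAAAATATCACAGTTTGGAATCGGTGATAT
parental_catalog:
  parentA: D. mixta
  parentB: D. valentini
  entries:
  - locus: Du215
    profile: TGC
    species: parentA
  - locus: Du215
    profile: ACT
    species: parentB
  - locus: Du281
    profile: T
    species: parentA
  - locus: Du281
    profile: C
    species: parentB
  - locus: Du323
    profile: CT
    cluster_signature: AC:5
    species: parentA
  - locus: Du323
    profile: AC
    cluster_signature: AC:6
    species: parentB
  - locus: Du47G
    profile: AAGA
    species: parentA
  - locus: Du47G
    profile: TTCA
    species: parentB
metadata:
  expected:
    n_individuals: 111
    n_genotypes: 13
    population_totals:
      Dsegh: 3
      Harich: 18
      Kuchak: 7
      Sevan: 1
      Lchashen: 1
      Meghradzor: 9
      Medved-gora: 12
      Dilijan: 4
      Pushkin-Pass: 7
      Dilijan-Semyonovka: 8
      Sotk: 3
      Stepanavan: 9
      Artavaz: 21
      Tezh: 8
  provenance: Reconstruction of a published 111-individual Darevskia armeniaca cohort
    at four sequenced microsatellite loci. Allele sequences are SYNTHETIC backbones
    carrying the reported repeat-cluster structure and flanking SNV profiles; flanks
    and exact coordinates are invented. Population placements of the minor cells of
    genotypes 2, 6, 7 and 9 were corroborated against per-population diversity indices
    rather than printed directly.
  flagged_inconsistencies:
  - source text places genotype 3 at Kuchak (5 of 8) and genotype 5 at Lchashen (7
    of 9); both contradict the table totals (Kuchak n=7, Lchashen n=1) and are placed
    at Dilijan-Semyonovka and Meghradzor respectively
  - published Dilijan-Semyonovka diversity cells correspond to a cohort retaining
    one homozygous-genotype individual and are not reproducible under the stated exclusion
    rule
  - published Du323 allelic-richness cells of Meghradzor and Medved-gora appear transposed
    (a value of 2.26 exceeds the printed allele count 2)
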