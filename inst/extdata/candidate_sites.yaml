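# Candidate amino-acid sites screened across species groups: four
# replacements reported in relation to cold adaptation and one in relation
# to high-altitude living. Sites are stored as gene-relative 1-based codon
# indices so that non-human genomes are callable; where the literature
# reports a human mitogenome nucleotide position, it is kept as metadata
# (human_pos, rCRS numbering).
sites:
  - gene: MT-ATP6
    codon: 59
    ref_residue: A
    variant_residues: [T]
    phenotype: cold_adaptation
    human_pos: 8701
  - gene: MT-ND3
    codon: 114
    ref_residue: T
    variant_residues: [A]
    phenotype: cold_adaptation
    human_pos: 10398
  - gene: MT-ND4
    codon: 29
    ref_residue: S
    variant_residues: [N]
    phenotype: cold_adaptation
  - gene: MT-ND5
    codon: 88
    ref_residue: V
    variant_residues: [I]
    phenotype: cold_adaptation
  - gene: MT-ND1
    codon: 30
    ref_residue: Y
    variant_residues: [C, H]
    phenotype: high_altitude
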