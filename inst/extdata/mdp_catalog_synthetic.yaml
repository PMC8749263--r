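# Synthetic reference catalog of the nine mitochondrial-derived peptide
# (MDP) sORF loci. Host genes, reading sense, peptide lengths and the
# start-codon behaviour of each locus follow the published biology of the
# human loci (MOTS-c in MT-RNR1; humanin and SHLP1-6 in MT-RNR2; gau on the
# antisense strand of MT-CO1; gau opens with ATA and is translatable only
# under the extended mitochondrial start repertoire; SHLP6's 3' end overlaps
# the conserved back-to-back primer motif). The nucleotide sequences are
# SYNTHETIC constructions (fixed codon choices), not the human reference
# mitogenome: coordinates and sequences here are data consumed by the
# pipeline, and a user with annotated real genomes should supply a catalog
# extracted from them.
default_code: standard
min_len: 8
max_len: 40
flank: 30
loci:
  - name: MOTS-c
    host: MT-RNR1
    sense: host_sense
    code: standard
    ref_nt: ATGCGATGGCAAGAAATGGGATACATCTTCTACCCACGAAAACTACGATAA
    ref_peptide: MRWQEMGYIFYPRKLR
  - name: humanin
    host: MT-RNR2
    sense: host_sense
    code: standard
    ref_nt: ATGGCACCACGAGGATTCTCATGCCTACTACTACTAACATCAGAAATCGATCTACCAGTAAAACGACGAGCATAA
    ref_peptide: MAPRGFSCLLLLTSEIDLPVKRRA
  - name: SHLP1
    host: MT-RNR2
    sense: host_sense
    code: standard
    ref_nt: ATGGTATCACGAGAACTATTCACAAACCCACTATCATGGGCAAAAGGAGATTTCTCACTAGTACGAAACGCATAA
    ref_peptide: MVSRELFTNPLSWAKGDFSLVRNA
  - name: SHLP2
    host: MT-RNR2
    sense: host_sense
    code: standard
    ref_nt: ATGCTAAACTGGGGAGAAACATTCAAACTATCACACGCAGTAGATCGACCAATCCAATCATGGATGGCAACAGGAAAATAA
    ref_peptide: MLNWGETFKLSHAVDRPIQSWMATGK
  - name: SHLP3
    host: MT-RNR2
    sense: host_sense
    code: standard
    ref_nt: ATGCTAGGAGTAAAACTATTCACACAACCATCACGAGATTGGGCAAACCACGAAATCCTATCAGGAGTAAAAACATTCGCACCACGAGATTACATGTCACTAAACTGCGGACAATAA
    ref_peptide: MLGVKLFTQPSRDWANHEILSGVKTFAPRDYMSLNCGQ
  - name: SHLP4
    host: MT-RNR2
    sense: host_sense
    code: standard
    ref_nt: ATGCTATACTCAACACTATCACCACAACTAAACCGATTCATGGATACAGTACTATCAAAAGCACCATGGCTACGATCATAA
    ref_peptide: MLYSTLSPQLNRFMDTVLSKAPWLRS
  - name: SHLP5
    host: MT-RNR2
    sense: host_sense
    code: standard
    ref_nt: ATGTTCGCACCAAAACTAGATTCATGGACAGGAAACGTACGAGAACTATCACACCAAATCGTAGCACCATGCTAA
    ref_peptide: MFAPKLDSWTGNVRELSHQIVAPC
  - name: SHLP6
    host: MT-RNR2
    sense: host_sense
    code: standard
    ref_nt: ATGCTAGATCAAGATATCCCAATGGTACAACCACTACTAAAAGTACGTTTGTTCAACGATTAA
    ref_peptide: MLDQDIPMVQPLLKVRLFND
  - name: gau
    host: MT-CO1
    sense: antisense
    code: standard
    start_policy_note: ATA start; translatable only with the extended start set
    ref_nt: ATACTATCACCAACACACCTACGAGCAAAATCAGCACTATTCTAA
    ref_peptide: MLSPTHLRAKSALF
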