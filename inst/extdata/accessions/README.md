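# Deposited 16S rRNA sequences (user-supplied)

The accession-dependent checks run on the 16S rRNA gene sequences deposited
in DDBJ/GenBank. Those sequences are not redistributed with this package;
fetch them yourself (e.g. with NCBI efetch) and place two plain-text FASTA
files in this directory:

- `LC314798.fasta` — the 1,499-bp symbiont 16S rRNA clone (accession
  LC314798), as a single unaligned record.
- `symbiont_16s_aligned.fasta` — an alignment of LC314798 (symbiont of
  *Oryzaephilus surinamensis*), LC310894 (symbiont of *Rhyzopertha
  dominica*) and NR_074784 (*Bacteroides fragilis*), with records named by
  accession. After complete-deletion filtering this alignment should retain
  roughly 1,425 sites.

Example download:

    efetch -db nuccore -id LC314798 -format fasta > LC314798.fasta
    efetch -db nuccore -id LC314798,LC310894,NR_074784 -format fasta \
      | mafft --auto - > symbiont_16s_aligned.fasta

With the files in place, `at_content()`, `ungapped_length()` and
`relative_rate_test()` can be checked against the published values
(AT 58.2%, 1,499 bp, K1 = 0.062, K2 = 0.134, K1/K2 = 0.46).
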